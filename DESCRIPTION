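Package: eQTLHotspots
Title: Cis/Trans eQTL Scanning and Regulatory Hotspot Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An additive allele-dosage linear eQTL scan with covariates for
    bulk RNA-seq cohorts, in the Matrix-eQTL tradition: genotype QC (minor
    allele frequency filtering, sliding-window linkage-disequilibrium
    pruning, near-gene restriction), expression filtering and median-of-ratios
    normalization, cis/trans classification at a configurable window,
    per-class Benjamini-Hochberg false discovery rates, gene-wise top-SNP
    reduction, cis and trans regulatory-hotspot discovery with
    permutation-based hotspot FDR, shared cis+trans hub flagging, and
    hypergeometric term enrichment with kappa-score clustering. Ships a
    seeded synthetic-cohort generator (Hardy-Weinberg genotypes with optional
    LD blocks, planted cis effects and trans master-regulator hubs, a latent
    Gaussian expression layer with negative-binomial counts) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    igraph
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'config.R'
    'eQTLHotspots-package.R'
    'preprocess.R'
    'scan.R'
    'enrichment.R'
    'hotspots.R'
    'io.R'
    'simulate.R'
    'pipeline.R'
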