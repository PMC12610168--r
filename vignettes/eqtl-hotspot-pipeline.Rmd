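---
title: "Methods: the cis/trans eQTL scan and hotspot pipeline"
author: "eQTLHotspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cis/trans eQTL scan and hotspot pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eQTLHotspots)
```

## The statistical model and its assumptions

The pipeline maps expression quantitative trait loci (eQTL) in a bulk
RNA-seq cohort: `n` diploid samples, each with hard-called genotypes
(allele dosages 0/1/2 from a VCF), a gene-level count matrix, and an age
covariate. For every SNP--gene pair the additive linear model

$$y_{g} = \mu + \beta \, d_{s} + \gamma \cdot \mathrm{age} + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2) \ \text{i.i.d.}$$

is fitted, with $d_s$ the ALT-allele count. The implementation
residualizes expression and dosages against the covariate design
(intercept + age) once, and obtains every pair's statistics from the
correlation of residuals (the Frisch--Waugh--Lovell identity guarantees
these equal the full model's genotype coefficient, its standard error, t
and p). This is the standard matrix formulation used by large-scale eQTL
engines, and it makes a full scan of $10^5$--$10^6$ pairs a few matrix
products.

Key assumptions, stated plainly:

* **Additivity.** Expression responds linearly in allele count. The
  generator can plant heterozygote-peak (overdominant) effects
  (`mode = "het_peak"`), but the scan analyzes them additively -- such
  effects lose power but are not special-cased, mirroring standard
  practice.
* **Independent residuals.** No kinship or mixed-model correction. Real
  cohorts of related animals violate this; the scan will be
  anti-conservative there. This is a documented limitation, not an option
  to toggle.
* **One covariate (age).** The design matrix is `cbind(1, age)`; degrees
  of freedom are `n - 3` at full data, reduced per pair under missing
  genotypes (pairwise deletion).

## Cis/trans classification

Distance between a SNP at 1-based position $p$ and a gene body
$[s, e]$ is $\max(s - p,\; p - e,\; 0)$: zero inside the gene, otherwise
base pairs to the nearer edge. A pair is **cis** iff SNP and gene share a
chromosome and the distance is at most the window (default 100,000 bp,
inclusive at the boundary: 100,000 is cis, 100,001 is trans). The anchor
is the gene body, not the TSS -- the window is read as gene proximity.
Everything else, including cross-chromosome pairs, is **trans**. Note this
is deliberately *not* the gap convention of `GenomicRanges::distance()`
(which counts an adjacent base as distance 0); the two differ by one base
for non-overlapping pairs, and the boundary rule above is the one applied
everywhere.

## Emission thresholds and FDR semantics

Only records below a per-class emission p-value threshold are
materialized: 0.02 for cis, 1e-6 for trans. These are *emission*
thresholds, not significance claims. Benjamini--Hochberg FDR is then
computed per class with `bhFdr(p, mTotal)`, where `mTotal` is the **total
number of tests in that class** -- not the number of emitted records.
Because every emitted record has a smaller p than every suppressed one,
the emitted records occupy the lowest ranks and the correction is exact.
Significance downstream means FDR <= 0.05. Cis and trans are corrected
separately because they are analyzed separately and have vastly different
test counts; the package reports both totals and their sum always equals
`nSnps * nGenes` (a conservation identity asserted by the tests).

Numerical details: p-values are reported as computed, never clamped to
zero from above; when a perfect correlation underflows the Student-t tail
to 0, the BH step substitutes the smallest representable positive double
for that record only. Zero-variance genotypes (monomorphic after QC or
within a pairwise-complete subset) yield `p = NA`, are never emitted, but
still count in the class totals.

## Preprocessing

**Expression.** Genes with total count < 200 or zero counts in >= 70 of 75
samples are dropped; for other cohort sizes the zero limit rescales as
`ceiling(70/75 * n)`. Normalization is median-of-ratios size factors
(genes containing any zero are excluded from the median) followed by
`log2(count / sf + 1)`. This is a variance-stabilizing *stand-in*: it
removes library-size differences exactly (size factors are defined up to a
common scale, so the normalized matrix is invariant up to a global
constant) and compresses the count--variance relationship, which is what
the linear scan needs. It is not the full DESeq2 VST; the package's tests
cross-check the size factors against DESeq2's estimator.

**Genotypes.** Three steps, in this order: (1) minor allele frequency
filter, strict -- MAF must exceed 0.01, so a SNP at exactly 0.01 is
removed, and monomorphic SNPs always are; MAF is
$\min(f, 1-f)$ with $f = \sum d / (2 n_{\text{nonmissing}})$;
(2) sliding-window LD pruning; (3) restriction to SNPs within the cis
window of an expressed gene (inclusive). Whether pruning should precede
or follow the near-gene restriction is genuinely open; the package fixes
MAF -> prune -> restrict and records the count surviving each step in a QC
report. One subtlety follows from that order: removing far-from-gene SNPs
changes which SNPs are window-neighbours, so re-pruning the *restricted*
panel can occasionally remove one more SNP. Each step is individually a
fixpoint (re-running it on its own output changes nothing), and that is
the property the tests assert.

**LD pruning.** PLINK-style `indep-pairwise` semantics: within each window
of 50 consecutive SNPs on a chromosome, any pair with dosage $r^2 \ge 0.2$
loses its later-positioned member (a deterministic tie-break); the window
advances by 5 SNPs; passes repeat until no SNP is removed, so no retained
within-window pair violates the threshold. $r^2$ is the squared Pearson
correlation of 0/1/2 dosage vectors, pairwise-complete over missing calls.
The 50/5 window/step are conventional defaults, configurable in
`eqtlConfig()`.

**Variant context.** A positional labeler assigns
genic(_exonic/_intronic)/upstream/downstream/intergenic by interval
arithmetic with strand-aware 5'/3' assignment (5 kb windows by default).
It is a deliberate stub: transcript-resolution effect prediction is out of
scope.

## Hotspots

Per SNP, the number of **distinct** genes with a significant association
(FDR <= 0.05) of the given class is counted; SNPs with none are absent
from the table.

* **Cis hotspots**: count >= 7 (inclusive).
* **Trans hotspot candidates**: count strictly greater than the 99th
  percentile of the per-SNP count distribution. The percentile uses
  linear interpolation between order statistics (R quantile type 7);
  strict exceedance implements "more than" semantics, so a degenerate
  all-equal distribution yields no candidates.

**Permutation test.** The null the hotspot statistic needs is "no
genotype--expression link, with LD and inter-gene correlation intact" --
a high per-SNP gene count can come from a block of co-expressed genes as
easily as from a true master regulator. Each of the B iterations therefore
applies *one shared permutation to the expression matrix's sample labels*
(all genes permuted together, preserving the expression correlation
structure and the genotype LD structure), rescans only the candidate SNPs
against all genes with the same trans emission threshold, applies BH
against the number of trans tests restricted to those SNPs, and records
each candidate's permuted regulated-gene count. Then

$$\text{perm}_p = \frac{1 + \#\{\text{permuted count} \ge
\text{observed count}\}}{B + 1},$$

the add-one estimator, which never returns 0 and lives on the grid
$\{(k+1)/(B+1)\}$ with minimum $1/(B+1)$ (9.9999e-6 at the full-scale
B = 100,000; about 1e-3 at the desk-scale B = 1000 used throughout the
tests). BH across the candidate set (m = number of candidates) gives the
hotspot q-values; significance is q < 0.05, strict. A plain BH estimator
is used; pi0-adjusted q-value estimators would give smaller values but
introduce an estimation step the candidate counts here are too small to
support. A trans hotspot whose SNP also has a significant cis record is
flagged a **shared hub**. Samples with a missing call at any candidate
SNP are dropped for the permutation analysis (complete-case); the main
scan itself uses pairwise deletion.

## Enrichment

Right-tailed hypergeometric over-representation of a query gene set
(typically the significant eGenes) against user-supplied GMT term
collections, with the background defaulting to all genes surviving the
expression filter. Both Bonferroni and BH corrections are reported.
Functionally related terms are grouped by Cohen's kappa on their binary
membership vectors over the background: terms with kappa >= 0.4 are
linked, and connected components with >= 2 terms form clusters while
singletons stay unclustered. Connected components are the simplest
reproducible reading of kappa-based term grouping; the iterative
leading-group merging some network tools apply is intentionally not
reproduced. Kappa is undefined (returned as NA) when chance agreement is
1, i.e. both terms empty or both equal to the background.

## The synthetic cohort generator

The generator emulates the study conditions the pipeline was built for --
75 animals, ages normal with mean 14.3 and SD 8.8 months truncated at 1
month, Hardy--Weinberg genotypes -- while staying small enough that the
whole pipeline runs in seconds:

* **Genome scaffold**: 5 chromosomes of 20 Mb, 300 non-overlapping genes
  (one per equal-width slot at a random offset, 5--30 kb long), 1500
  uniform SNP positions plus one guaranteed SNP inside each gene body so
  every gene has a cis candidate.
* **Genotypes**: per-SNP allele frequency uniform on [0.05, 0.5];
  optional LD blocks in which members copy a founder's alleles with
  per-site redraw probability 0.1 (preserving the marginal frequency
  while making within-block $r^2$ high) -- the simplest mechanism that
  makes pruning meaningful; defaults to independent SNPs.
* **Effects**: a quarter of genes get one cis effect from a SNP within
  the window, effect sizes N(0, 1.5^2) latent-SD units; two trans
  master-regulator hubs with 40 and 16 distant targets (betas N(0,
  1.5^2)); 30 singleton trans effects that give the per-SNP count
  distribution the "most SNPs regulate one gene, a few regulate many"
  skew the 99th-percentile rule presumes; the larger hub also receives a
  strong cis effect (|beta| = 3) so it presents as a shared cis+trans
  hub, the convergence pattern of a genuine master regulator.
* **Expression**: latent layer `baseline + effects + ageBeta*age +
  N(0,1)` (age effect defaults to 0 -- its magnitude is not part of the
  emulated conditions); the count layer draws negative binomial with mean
  `libSize * exp(latent)/colSum` (library sizes 0.8--1.2 million over 300
  genes, matching deep bulk RNA-seq scaled to the reduced gene count) and
  dispersion 0.1.

The truth table (`snp_id, gene_id, mode, beta, class`) is the generator's
ledger; every planted cis pair satisfies the scan's cis predicate and
every trans pair fails it, by construction and by cross-validated test.

**What passing tests do and do not show.** The generator has no
relatedness, no population stratification, no realistic haplotype
structure, no sex chromosomes, and additive noise that is exactly
Gaussian on the latent scale. Tests passing here certify the machinery --
estimator correctness, FDR semantics, recovery power at planted effect
sizes -- not robustness to the confounders of real cohorts.

## Problem sizes and tolerances in the tests

The acceptance-grade checks use, as the package's own choices: a 75 x
(500 genes x ~2,500 SNPs) panel for engine--oracle equivalence at 1e-8
against per-pair `lm()` fits; 1,000 random vectors for exact BH
agreement; 20 null cohorts (50 genes, 200 SNPs) for FDR calibration
(mean false-eGene proportion <= 0.07, a Monte-Carlo tolerance above the
nominal 0.05); 50 seeds for cis-effect recovery (planted beta = 1.5,
MAF 0.3 -- recovered within 10%, top-SNP rate >= 95%); 10 planted-hub and
20 null cohorts at B = 1,000 for hotspot power and validity; and 100
seeded panels for prune soundness. Scan-stage tests consume the latent
expression matrix directly, decoupling association error from
normalization error; the end-to-end pipeline tests exercise the
counts-plus-normalization route.

## Known limitations

* No mixed-model/kinship correction; no conditional or secondary-signal
  analysis; dominance is generated but not modeled.
* The normalization is a documented VST stand-in, exact only in its
  library-size invariance.
* Multi-allelic VCF records are rejected (or dropped on request), not
  split.
* The permutation null conditions on the observed candidate set;
  candidates are not re-selected within permutations.
* Percentile-based candidate selection is coarse when few SNPs carry any
  significant trans record, as at desk scale: with a single dominant hub
  and a handful of singleton SNPs the cutoff sits between them, which is
  the intended behavior, but a second, smaller hub can fall below the
  cutoff.
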