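#' @include AllClasses.R config.R io.R simulate.R preprocess.R scan.R hotspots.R enrichment.R
NULL

#' Run the whole pipeline on one directory
#'
#' Chains the stages end to end: simulate (unless the input files already
#' exist in \code{dir}), preprocess, scan, hotspot discovery, and optional
#' term enrichment, writing every intermediate and result table as TSV/VCF
#' under \code{dir}. With a fixed seed and config the run is fully
#' deterministic (identical output files).
#'
#' Files written: \code{genotypes.vcf}, \code{gene_models.tsv},
#' \code{counts.tsv}, \code{covariates.tsv}, \code{truth.tsv} (inputs);
#' \code{expression_normalized.tsv}, \code{qc_report.tsv},
#' \code{cis_associations.tsv}, \code{trans_associations.tsv},
#' \code{top_pairs.tsv}, \code{qq_cis.tsv}, \code{qq_trans.tsv},
#' \code{test_counts.tsv}, \code{hotspots.tsv} and, when a GMT file is
#' given, \code{enrichment.tsv}.
#'
#' @param dir output directory (created if needed).
#' @param config an \linkS4class{EQTLConfig}.
#' @param B permutation count for the hotspot FDR (desk-scale default 1000).
#' @param gmtPath optional path to a GMT term collection; enrichment runs on
#'   the significant eGenes against the expressed-gene background.
#' @param seed integer seed driving simulation and permutation.
#' @param simArgs list of overrides passed to \code{\link{simulateStudy}}.
#' @return Invisibly, a list with the scan result, hotspot tables, QC
#'   report, and file paths.
#' @export
runPipeline <- function(dir, config = eqtlConfig(), B = 1000L,
                        gmtPath = NULL, seed = config@seed,
                        simArgs = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)

  inputFiles <- c("genotypes.vcf", "gene_models.tsv", "counts.tsv",
                  "covariates.tsv")
  if (!all(file.exists(vapply(inputFiles, path, character(1))))) {
    study <- do.call(simulateStudy,
                     c(list(config = config, seed = seed), simArgs))
    writeVcfDosage(study$geno, path("genotypes.vcf"))
    writeGeneModels(study$genes, path("gene_models.tsv"))
    writeMatrixTSV(study$counts, path("counts.tsv"))
    writeCovariates(study$covariates, path("covariates.tsv"))
    writeEffectTruth(study$truth, path("truth.tsv"))
  }

  geno <- readVcfDosage(path("genotypes.vcf"))
  genes <- readGeneModels(path("gene_models.tsv"))
  counts <- readMatrixTSV(path("counts.tsv"))
  covariates <- readCovariates(path("covariates.tsv"))

  prep <- preprocessStudy(counts, geno, genes, config)
  writeMatrixTSV(round(prep$expr, 6), path("expression_normalized.tsv"))
  writeResultTable(prep$qc, path("qc_report.tsv"))

  scan <- scanAssociations(prep$expr, prep$geno, covariates, prep$genes,
                           config)
  writeResultTable(cisAssociations(scan), path("cis_associations.tsv"))
  writeResultTable(transAssociations(scan), path("trans_associations.tsv"))
  top <- topPerGene(cisAssociations(scan), config@fdrMax)
  writeResultTable(top, path("top_pairs.tsv"))
  if (nrow(cisAssociations(scan))) {
    writeResultTable(qqData(cisAssociations(scan)$p), path("qq_cis.tsv"))
  }
  if (nrow(transAssociations(scan))) {
    writeResultTable(qqData(transAssociations(scan)$p), path("qq_trans.tsv"))
  }
  tc <- testCounts(scan)
  writeResultTable(data.frame(class = names(tc), n_tests = unname(tc)),
                   path("test_counts.tsv"))

  cisCounts <- countRegulatedGenes(cisAssociations(scan), config@fdrMax)
  cisHs <- cisHotspots(cisCounts, config@cisHotspotMinGenes)
  transHs <- findTransHotspots(scan, prep$expr, prep$geno, covariates,
                               prep$genes, B = B, config = config,
                               seed = seed + 5L)
  hotspots <- rbind(
    cbind(cisHs, significant = rep(NA, nrow(cisHs))),
    transHs)
  writeResultTable(hotspots, path("hotspots.tsv"))

  enrichment <- NULL
  if (!is.null(gmtPath)) {
    terms <- readGmt(gmtPath)
    backgroundGenes <- rownames(prep$expr)
    query <- intersect(unique(top$gene_id), backgroundGenes)
    if (length(query)) {
      enrichment <- enrichTerms(query, terms, backgroundGenes,
                                config@kappaMin)
      writeResultTable(enrichment, path("enrichment.tsv"))
    }
  }

  invisible(list(scan = scan, topPairs = top, cisHotspots = cisHs,
                 transHotspots = transHs, qc = prep$qc,
                 enrichment = enrichment, dir = dir))
}
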