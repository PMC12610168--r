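#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges granges seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges colData
NULL

#' Pipeline configuration
#'
#' Holds every tunable threshold of the pipeline. The defaults reproduce the
#' study settings of the backfat eQTL analysis this package implements:
#' a +/-100 kb cis window, emission thresholds p < 0.02 (cis) and p < 1e-6
#' (trans), significance at FDR <= 0.05, MAF > 0.01 (strict), LD pruning at
#' r^2 < 0.2 in 50-SNP windows stepping by 5, expression filters (total
#' count < 200 dropped; zero counts in >= 70 of 75 samples dropped), cis
#' hotspots at >= 7 unique genes, trans hotspots above the 99th percentile of
#' per-SNP regulated-gene counts, and 100,000 permutations for hotspot FDR.
#'
#' @slot cisWindow numeric(1) cis window in base pairs.
#' @slot pCis numeric(1) cis emission p-value threshold.
#' @slot pTrans numeric(1) trans emission p-value threshold.
#' @slot fdrMax numeric(1) significance FDR cutoff.
#' @slot mafMin numeric(1) minimum minor allele frequency (strict >).
#' @slot ldR2Max numeric(1) LD pruning r^2 threshold (pairs at or above are
#'   pruned).
#' @slot ldWindowSnps integer(1) SNPs per pruning window.
#' @slot ldStepSnps integer(1) SNPs to advance the window.
#' @slot minGeneTotal numeric(1) minimum total read count per gene.
#' @slot zeroSampleLimit numeric(1) genes with at least this many zero-count
#'   samples are dropped; \code{NA} means derive from the sample count
#'   (ceiling of 70/75 * n).
#' @slot cisHotspotMinGenes integer(1) minimum unique genes for a cis hotspot.
#' @slot transHotspotPercentile numeric(1) percentile (0-100) of the per-SNP
#'   regulated-gene count distribution defining trans hotspot candidates.
#' @slot nPermutations integer(1) permutation count for hotspot FDR.
#' @slot kappaMin numeric(1) kappa threshold linking enrichment terms.
#' @slot seed integer(1) base seed for stochastic stages.
#' @exportClass EQTLConfig
setClass("EQTLConfig",
  representation(
    cisWindow = "numeric",
    pCis = "numeric",
    pTrans = "numeric",
    fdrMax = "numeric",
    mafMin = "numeric",
    ldR2Max = "numeric",
    ldWindowSnps = "integer",
    ldStepSnps = "integer",
    minGeneTotal = "numeric",
    zeroSampleLimit = "numeric",
    cisHotspotMinGenes = "integer",
    transHotspotPercentile = "numeric",
    nPermutations = "integer",
    kappaMin = "numeric",
    seed = "integer"
  )
)

setValidity("EQTLConfig", function(object) {
  msg <- character(0)
  probs <- c(pCis = object@pCis, pTrans = object@pTrans, fdrMax = object@fdrMax)
  bad <- probs <= 0 | probs > 1
  if (any(bad)) {
    msg <- c(msg, sprintf("probability thresholds must lie in (0, 1]: %s",
                          paste(names(probs)[bad], collapse = ", ")))
  }
  if (object@cisWindow < 0) msg <- c(msg, "cisWindow must be >= 0")
  if (object@mafMin < 0 || object@mafMin >= 0.5) {
    msg <- c(msg, "mafMin must lie in [0, 0.5)")
  }
  if (object@ldR2Max <= 0 || object@ldR2Max > 1) {
    msg <- c(msg, "ldR2Max must lie in (0, 1]")
  }
  if (object@ldWindowSnps < 2L) msg <- c(msg, "ldWindowSnps must be >= 2")
  if (object@ldStepSnps < 1L) msg <- c(msg, "ldStepSnps must be >= 1")
  if (object@transHotspotPercentile <= 0 || object@transHotspotPercentile >= 100) {
    msg <- c(msg, "transHotspotPercentile must lie in (0, 100)")
  }
  if (object@cisHotspotMinGenes < 1L) msg <- c(msg, "cisHotspotMinGenes must be >= 1")
  if (object@nPermutations < 1L) msg <- c(msg, "nPermutations must be >= 1")
  if (object@kappaMin < -1 || object@kappaMin > 1) {
    msg <- c(msg, "kappaMin must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Genotype container: variants x samples allele dosages
#'
#' A \linkS4class{RangedSummarizedExperiment} whose rows are biallelic
#' variants (width-1 \code{GRanges} with \code{snp_id}, \code{ref},
#' \code{alt}, and optionally \code{maf} in \code{mcols}) and whose single
#' assay \code{"dosage"} counts copies of the ALT allele (0, 1, 2; \code{NA}
#' for missing calls).
#'
#' @exportClass GenotypeExperiment
setClass("GenotypeExperiment",
  contains = "RangedSummarizedExperiment")

setValidity("GenotypeExperiment", function(object) {
  msg <- character(0)
  if (!"dosage" %in% SummarizedExperiment::assayNames(object)) {
    return("assay 'dosage' is required")
  }
  d <- SummarizedExperiment::assay(object, "dosage")
  vals <- d[!is.na(d)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  md <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))
  need <- c("snp_id", "ref", "alt")
  miss <- setdiff(need, colnames(md))
  if (length(miss)) {
    msg <- c(msg, sprintf("rowRanges mcols must contain: %s",
                          paste(miss, collapse = ", ")))
  } else if (anyDuplicated(md$snp_id)) {
    msg <- c(msg, "snp_id must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a cis/trans eQTL scan
#'
#' Bundles the emitted cis and trans association records together with the
#' total number of tests performed per class (used for the per-class
#' Benjamini-Hochberg correction) and the configuration that produced them.
#'
#' @slot cis data.frame of emitted cis records (p below the cis emission
#'   threshold), one row per SNP-gene pair.
#' @slot trans data.frame of emitted trans records.
#' @slot nCisTests numeric(1) total cis pairs tested.
#' @slot nTransTests numeric(1) total trans pairs tested.
#' @slot config the \linkS4class{EQTLConfig} used.
#' @exportClass EQTLScanResult
setClass("EQTLScanResult",
  representation(
    cis = "data.frame",
    trans = "data.frame",
    nCisTests = "numeric",
    nTransTests = "numeric",
    config = "EQTLConfig"
  )
)

setValidity("EQTLScanResult", function(object) {
  cols <- assocRecordColumns()
  msg <- character(0)
  for (slot in c("cis", "trans")) {
    df <- slot(object, slot)
    miss <- setdiff(cols, colnames(df))
    if (length(miss)) {
      msg <- c(msg, sprintf("%s table lacks columns: %s", slot,
                            paste(miss, collapse = ", ")))
    }
  }
  if (object@nCisTests < 0 || object@nTransTests < 0) {
    msg <- c(msg, "test counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

assocRecordColumns <- function() {
  c("snp_id", "gene_id", "beta", "se", "t", "p", "fdr", "class",
    "distance", "var_explained", "ci95_low", "ci95_high")
}
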