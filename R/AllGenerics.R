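#' @include AllClasses.R
NULL

#' Accessors for scan results and genotype containers
#'
#' \code{dosage} returns the variants x samples dosage matrix;
#' \code{variantInfo} the variant table (GRanges mcols plus coordinates) as a
#' data.frame; \code{cisAssociations}/\code{transAssociations} the emitted
#' association records; \code{testCounts} the per-class totals used for the
#' Benjamini-Hochberg correction.
#'
#' @param object a \linkS4class{GenotypeExperiment} or
#'   \linkS4class{EQTLScanResult}.
#' @return See the individual accessor descriptions.
#' @name accessors
#' @aliases dosage variantInfo cisAssociations transAssociations testCounts
NULL

#' @rdname accessors
#' @export
setGeneric("dosage", function(object) standardGeneric("dosage"))

#' @rdname accessors
#' @export
setGeneric("variantInfo", function(object) standardGeneric("variantInfo"))

#' @rdname accessors
#' @export
setGeneric("cisAssociations", function(object) standardGeneric("cisAssociations"))

#' @rdname accessors
#' @export
setGeneric("transAssociations", function(object) standardGeneric("transAssociations"))

#' @rdname accessors
#' @export
setGeneric("testCounts", function(object) standardGeneric("testCounts"))

#' @rdname accessors
#' @export
setMethod("dosage", "GenotypeExperiment", function(object) {
  SummarizedExperiment::assay(object, "dosage")
})

#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypeExperiment", function(object) {
  rr <- SummarizedExperiment::rowRanges(object)
  md <- as.data.frame(S4Vectors::mcols(rr))
  out <- data.frame(
    snp_id = md$snp_id,
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = md$ref,
    alt = md$alt,
    stringsAsFactors = FALSE
  )
  if ("maf" %in% colnames(md)) out$maf <- md$maf
  rownames(out) <- NULL
  out
})

#' @rdname accessors
#' @export
setMethod("cisAssociations", "EQTLScanResult", function(object) object@cis)

#' @rdname accessors
#' @export
setMethod("transAssociations", "EQTLScanResult", function(object) object@trans)

#' @rdname accessors
#' @export
setMethod("testCounts", "EQTLScanResult", function(object) {
  c(cis = object@nCisTests, trans = object@nTransTests)
})

setMethod("show", "EQTLConfig", function(object) {
  cat("EQTLConfig\n")
  cat(sprintf("  cis window           : %s bp\n", format(object@cisWindow, big.mark = ",")))
  cat(sprintf("  emission p (cis/trans): %g / %g\n", object@pCis, object@pTrans))
  cat(sprintf("  significance FDR     : %g\n", object@fdrMax))
  cat(sprintf("  MAF > %g; LD prune r2 >= %g (window %d, step %d)\n",
              object@mafMin, object@ldR2Max, object@ldWindowSnps, object@ldStepSnps))
  cat(sprintf("  gene filters: total < %g or zeros >= %s dropped\n",
              object@minGeneTotal,
              ifelse(is.na(object@zeroSampleLimit), "ceil(70/75*n)",
                     format(object@zeroSampleLimit))))
  cat(sprintf("  hotspots: cis >= %d genes; trans > %gth percentile; B = %s\n",
              object@cisHotspotMinGenes, object@transHotspotPercentile,
              format(object@nPermutations, big.mark = ",")))
  cat(sprintf("  kappa threshold %g; seed %d\n", object@kappaMin, object@seed))
})

setMethod("show", "GenotypeExperiment", function(object) {
  d <- dosage(object)
  cat(sprintf("GenotypeExperiment: %d variants x %d samples\n",
              nrow(d), ncol(d)))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", sum(is.na(d)),
              100 * mean(is.na(d))))
  chroms <- unique(as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(object))))
  cat(sprintf("  chromosomes: %s\n", paste(chroms, collapse = ", ")))
})

setMethod("show", "EQTLScanResult", function(object) {
  cat("EQTLScanResult\n")
  cat(sprintf("  cis : %d emitted records of %s tests (%d at FDR <= %g)\n",
              nrow(object@cis), format(object@nCisTests, big.mark = ","),
              sum(object@cis$fdr <= object@config@fdrMax),
              object@config@fdrMax))
  cat(sprintf("  trans: %d emitted records of %s tests (%d at FDR <= %g)\n",
              nrow(object@trans), format(object@nTransTests, big.mark = ","),
              sum(object@trans$fdr <= object@config@fdrMax),
              object@config@fdrMax))
})
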