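#' @include AllClasses.R
NULL

#' Create a pipeline configuration
#'
#' The defaults are the study settings this package implements (see
#' \linkS4class{EQTLConfig}). \code{zeroSampleLimit = NA} derives the limit
#' from the sample count at filter time as \code{ceiling(70/75 * n)}, which
#' equals the study's 70 at n = 75.
#'
#' @param cisWindow cis window in base pairs (default 100000).
#' @param pCis,pTrans per-class emission p-value thresholds (defaults 0.02
#'   and 1e-6).
#' @param fdrMax significance FDR cutoff (default 0.05).
#' @param mafMin minor allele frequency threshold, strict (default 0.01).
#' @param ldR2Max LD pruning r^2 threshold (default 0.2).
#' @param ldWindowSnps,ldStepSnps pruning window size and step in SNPs
#'   (defaults 50 and 5, the conventional PLINK values).
#' @param minGeneTotal minimum total read count per gene (default 200).
#' @param zeroSampleLimit zero-count sample limit (default NA: derived).
#' @param cisHotspotMinGenes minimum unique genes for a cis hotspot
#'   (default 7).
#' @param transHotspotPercentile percentile defining trans hotspot
#'   candidates (default 99).
#' @param nPermutations permutations for hotspot FDR (default 100000; tests
#'   and desk-scale runs pass a smaller B explicitly).
#' @param kappaMin kappa threshold linking enrichment terms (default 0.4).
#' @param seed base seed (default 1).
#' @return A validated \linkS4class{EQTLConfig}.
#' @examples
#' cfg <- eqtlConfig()
#' cfg
#' @export
eqtlConfig <- function(cisWindow = 100000,
                       pCis = 0.02,
                       pTrans = 1e-6,
                       fdrMax = 0.05,
                       mafMin = 0.01,
                       ldR2Max = 0.2,
                       ldWindowSnps = 50L,
                       ldStepSnps = 5L,
                       minGeneTotal = 200,
                       zeroSampleLimit = NA_real_,
                       cisHotspotMinGenes = 7L,
                       transHotspotPercentile = 99,
                       nPermutations = 100000L,
                       kappaMin = 0.4,
                       seed = 1L) {
  new("EQTLConfig",
      cisWindow = as.numeric(cisWindow),
      pCis = as.numeric(pCis),
      pTrans = as.numeric(pTrans),
      fdrMax = as.numeric(fdrMax),
      mafMin = as.numeric(mafMin),
      ldR2Max = as.numeric(ldR2Max),
      ldWindowSnps = as.integer(ldWindowSnps),
      ldStepSnps = as.integer(ldStepSnps),
      minGeneTotal = as.numeric(minGeneTotal),
      zeroSampleLimit = as.numeric(zeroSampleLimit),
      cisHotspotMinGenes = as.integer(cisHotspotMinGenes),
      transHotspotPercentile = as.numeric(transHotspotPercentile),
      nPermutations = as.integer(nPermutations),
      kappaMin = as.numeric(kappaMin),
      seed = as.integer(seed))
}

# Effective zero-sample limit for a cohort of n samples.
effectiveZeroLimit <- function(config, n) {
  if (is.na(config@zeroSampleLimit)) ceiling(70 / 75 * n)
  else config@zeroSampleLimit
}
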