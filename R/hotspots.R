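#' @include AllClasses.R config.R scan.R
#' @importFrom stats quantile
NULL

#' Count unique significantly regulated genes per SNP
#'
#' For each SNP with at least one record at \code{fdr <= fdrMax}, counts the
#' distinct gene ids among its significant records. SNPs with no significant
#' record are absent from the table. Counting is invariant to record order
#' and duplicated SNP-gene rows.
#'
#' @param records association data.frame (one class: cis or trans).
#' @param fdrMax significance cutoff.
#' @param class optional filter on the \code{class} column.
#' @return data.frame with \code{snp_id} and \code{n_genes}, sorted by
#'   decreasing count.
#' @export
countRegulatedGenes <- function(records, fdrMax = 0.05, class = NULL) {
  if (!is.null(class)) {
    records <- records[records$class == class, , drop = FALSE]
  }
  sig <- records[!is.na(records$fdr) & records$fdr <= fdrMax, , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(snp_id = character(0), n_genes = integer(0),
                      stringsAsFactors = FALSE))
  }
  sig <- unique(sig[, c("snp_id", "gene_id")])
  tab <- table(sig$snp_id)
  out <- data.frame(snp_id = names(tab), n_genes = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_genes, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cis regulatory hotspots
#'
#' SNPs whose count of unique significantly cis-regulated genes is at least
#' \code{minGenes} (inclusive; default 7).
#'
#' @param countTable output of \code{\link{countRegulatedGenes}} on cis
#'   records.
#' @param minGenes minimum unique gene count.
#' @return Hotspot data.frame (\code{snp_id, class, n_genes, perm_p, q,
#'   shared_hub}); permutation columns are NA for cis hotspots.
#' @export
cisHotspots <- function(countTable, minGenes = 7L) {
  sel <- countTable[countTable$n_genes >= minGenes, , drop = FALSE]
  data.frame(snp_id = sel$snp_id, class = rep("cis", nrow(sel)),
             n_genes = sel$n_genes, perm_p = rep(NA_real_, nrow(sel)),
             q = rep(NA_real_, nrow(sel)),
             shared_hub = rep(NA, nrow(sel)), stringsAsFactors = FALSE)
}

#' Trans hotspot candidate cutoff
#'
#' The given percentile of the per-SNP regulated-gene count distribution
#' (linear interpolation between order statistics, quantile type 7).
#' Candidates are SNPs whose count STRICTLY exceeds the cutoff ("more than"
#' semantics).
#'
#' @param countTable output of \code{\link{countRegulatedGenes}} on trans
#'   records; must be nonempty.
#' @param percentile percentile in (0, 100), default 99.
#' @return The numeric cutoff.
#' @export
transHotspotCutoff <- function(countTable, percentile = 99) {
  if (!nrow(countTable)) stop("empty count table: no trans-regulating SNPs")
  unname(quantile(countTable$n_genes, percentile / 100, type = 7))
}

#' Trans hotspot candidates
#'
#' @inheritParams transHotspotCutoff
#' @return The subset of \code{countTable} with \code{n_genes} strictly
#'   above the cutoff; the cutoff is attached as attribute \code{"cutoff"}.
#' @export
transHotspotCandidates <- function(countTable, percentile = 99) {
  cutoff <- transHotspotCutoff(countTable, percentile)
  out <- countTable[countTable$n_genes > cutoff, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  out
}

#' Permutation p-value on the (r + 1) / (B + 1) grid
#'
#' The add-one estimator never returns 0; the smallest attainable value is
#' \code{1 / (B + 1)} (9.9999e-6 at B = 100000, i.e. 0.00001 at five
#' decimals).
#'
#' @param nExceed number of permutations with a statistic at least the
#'   observed one.
#' @param B number of permutations.
#' @return \code{(nExceed + 1) / (B + 1)}.
#' @export
permPValue <- function(nExceed, B) {
  (nExceed + 1) / (B + 1)
}

#' Permutation test for trans hotspot counts
#'
#' Each of the \code{B} iterations applies one shared random permutation to
#' the sample labels of the expression matrix (preserving genotype LD and
#' inter-gene correlation), rescans only the candidate SNPs against all
#' genes with the trans pipeline (same emission threshold; BH against the
#' number of trans tests restricted to the candidate SNPs), and records each
#' candidate's permuted regulated-gene count. The permutation p-value is
#' \code{(1 + #\{permuted count >= observed\}) / (B + 1)}.
#'
#' Samples with a missing call at any candidate SNP are dropped for the
#' whole permutation analysis (complete-case, documented simplification).
#'
#' @param expr genes x samples normalized expression matrix.
#' @param geno a \linkS4class{GenotypeExperiment}.
#' @param covariates data.frame with \code{sample_id}, \code{age}.
#' @param genes GRanges covering \code{rownames(expr)}.
#' @param candidateSnpIds character vector of candidate hotspot snp_ids.
#' @param observedCounts named integer vector (names = snp_id) of observed
#'   regulated-gene counts from the main scan.
#' @param B number of permutations.
#' @param config an \linkS4class{EQTLConfig}.
#' @param seed integer seed for the permutation stream.
#' @return data.frame with \code{snp_id}, \code{n_genes} (observed),
#'   \code{perm_p}.
#' @export
hotspotPermutationTest <- function(expr, geno, covariates, genes,
                                   candidateSnpIds, observedCounts, B,
                                   config = eqtlConfig(), seed = config@seed) {
  if (!length(candidateSnpIds)) stop("no candidate SNPs supplied")
  if (B < 1L) stop("B must be >= 1")
  if (1 / (B + 1) > config@fdrMax) {
    warning("B = ", B, " cannot reach perm_p below the FDR target ",
            config@fdrMax)
  }
  d <- dosage(geno)
  vi <- variantInfo(geno)
  sel <- match(candidateSnpIds, vi$snp_id)
  if (anyNA(sel)) stop("candidate snp_id(s) not in genotypes")
  samples <- colnames(expr)
  if (!setequal(samples, colnames(d)) ||
      !setequal(samples, covariates$sample_id)) {
    stop("alignment error: expression, genotype and covariate samples differ")
  }
  dC <- d[sel, samples, drop = FALSE]
  ok <- colSums(is.na(dC)) == 0L
  dC <- dC[, ok, drop = FALSE]
  expr <- expr[, ok, drop = FALSE]
  samples <- samples[ok]
  age <- covariates$age[match(samples, covariates$sample_id)]
  n <- length(samples)
  X <- cbind(intercept = 1, age = age)
  df <- n - ncol(X) - 1L
  if (df < 1L) stop("too few complete samples for the permutation test")

  gIdx <- match(rownames(expr), S4Vectors::mcols(genes)$gene_id)
  if (anyNA(gIdx)) stop("alignment error: expression rows missing from gene models")
  genes <- genes[gIdx]
  gChrom <- as.character(GenomicRanges::seqnames(genes))
  gStart <- GenomicRanges::start(genes)
  gEnd <- GenomicRanges::end(genes)
  nG <- nrow(expr); k <- length(sel)

  vChrom <- vi$chrom[sel]; vPos <- vi$pos[sel]
  distMat <- pmax(outer(gStart, vPos, "-"), outer(gEnd, vPos, function(a, b) b - a), 0)
  transMask <- !(outer(gChrom, vChrom, "==") & distMat <= config@cisWindow)
  mTrans <- sum(transMask)

  G <- residualize(dC, X)
  gNorm <- sqrt(rowSums(G^2))
  live <- gNorm > 0
  Gs <- G / ifelse(gNorm == 0, 1, gNorm)

  qrX <- qr(X)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  projOut <- function(m) m - (m %*% Q) %*% t(Q)

  obs <- observedCounts[candidateSnpIds]
  obs[is.na(obs)] <- 0L
  exceed <- integer(k)
  set.seed(as.integer(seed))
  for (it in seq_len(B)) {
    perm <- sample.int(n)
    Ep <- projOut(expr[, perm, drop = FALSE])
    en <- sqrt(rowSums(Ep^2))
    Es <- Ep / ifelse(en == 0, 1, en)
    R <- Es %*% t(Gs)
    tM <- R * sqrt(df / pmax(1 - R^2, .Machine$double.eps))
    pM <- 2 * pt(abs(tM), df, lower.tail = FALSE)
    selEmit <- which(transMask & pM < config@pTrans &
                       rep(live, each = nG))
    counts <- integer(k)
    if (length(selEmit)) {
      fdr <- bhFdr(pmax(pM[selEmit], .Machine$double.xmin), mTrans)
      keep <- fdr <= config@fdrMax
      if (any(keep)) {
        vj <- ((selEmit[keep] - 1L) %/% nG) + 1L
        tab <- table(vj)
        counts[as.integer(names(tab))] <- as.integer(tab)
      }
    }
    exceed <- exceed + as.integer(counts >= obs)
  }
  data.frame(snp_id = candidateSnpIds, n_genes = as.integer(obs),
             perm_p = permPValue(exceed, B), stringsAsFactors = FALSE)
}

#' BH correction of hotspot permutation p-values
#'
#' BH across the candidate set (m = number of candidates); a hotspot is
#' significant when q is strictly below \code{fdrMax}.
#'
#' @param permP permutation p-values.
#' @param fdrMax significance cutoff (default 0.05).
#' @return list with \code{q} and logical \code{significant}.
#' @export
hotspotFdr <- function(permP, fdrMax = 0.05) {
  q <- bhFdr(permP, length(permP))
  list(q = q, significant = q < fdrMax)
}

#' Flag shared cis + trans regulatory hubs
#'
#' A trans hotspot is a shared hub when the same SNP also has at least one
#' significant cis record (\code{fdr <= fdrMax}).
#'
#' @param hotspots hotspot data.frame with \code{snp_id}.
#' @param cisRecords cis association data.frame.
#' @param fdrMax significance cutoff.
#' @return \code{hotspots} with \code{shared_hub} set.
#' @export
flagSharedHubs <- function(hotspots, cisRecords, fdrMax = 0.05) {
  cisSnps <- unique(cisRecords$snp_id[!is.na(cisRecords$fdr) &
                                        cisRecords$fdr <= fdrMax])
  hotspots$shared_hub <- hotspots$snp_id %in% cisSnps
  hotspots
}

#' Full trans-hotspot discovery from a scan result
#'
#' Chains per-SNP gene counting, the percentile candidate rule, the
#' permutation test, BH across candidates, and shared-hub flagging.
#'
#' @param scanResult an \linkS4class{EQTLScanResult}.
#' @param expr,geno,covariates,genes the scan inputs (for the permutation
#'   rescans).
#' @param B number of permutations.
#' @param config an \linkS4class{EQTLConfig}.
#' @param seed permutation seed.
#' @return Hotspot data.frame (\code{snp_id, class, n_genes, perm_p, q,
#'   shared_hub, significant}) with the candidate cutoff attached as
#'   attribute \code{"cutoff"}; zero rows when there are no candidates.
#' @export
findTransHotspots <- function(scanResult, expr, geno, covariates, genes,
                              B = 1000L, config = scanResult@config,
                              seed = config@seed) {
  empty <- data.frame(snp_id = character(0), class = character(0),
                      n_genes = integer(0), perm_p = numeric(0),
                      q = numeric(0), shared_hub = logical(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  counts <- countRegulatedGenes(transAssociations(scanResult),
                                config@fdrMax)
  if (!nrow(counts)) return(empty)
  cand <- transHotspotCandidates(counts, config@transHotspotPercentile)
  if (!nrow(cand)) {
    attr(empty, "cutoff") <- attr(cand, "cutoff")
    return(empty)
  }
  obs <- stats::setNames(cand$n_genes, cand$snp_id)
  perm <- hotspotPermutationTest(expr, geno, covariates, genes,
                                 cand$snp_id, obs, B, config, seed)
  fdr <- hotspotFdr(perm$perm_p, config@fdrMax)
  out <- data.frame(snp_id = perm$snp_id, class = "trans",
                    n_genes = perm$n_genes, perm_p = perm$perm_p,
                    q = fdr$q, shared_hub = NA,
                    significant = fdr$significant, stringsAsFactors = FALSE)
  out <- flagSharedHubs(out, cisAssociations(scanResult), config@fdrMax)
  attr(out, "cutoff") <- attr(cand, "cutoff")
  out
}
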