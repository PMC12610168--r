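#' @include AllClasses.R config.R preprocess.R
#' @importFrom stats pt qt p.adjust
NULL

#' Residualize rows of a matrix against a covariate design
#'
#' Projects each row of \code{mat} (features x samples) onto the orthogonal
#' complement of the column space of \code{design} (samples x covariates,
#' intercept included). Residual rows are orthogonal to every covariate
#' column.
#'
#' @param mat features x samples numeric matrix.
#' @param design samples x covariates design matrix including the intercept.
#' @return The residualized matrix, same shape as \code{mat}.
#' @export
residualize <- function(mat, design) {
  design <- as.matrix(design)
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    stop("collinearity error: covariate design is rank-deficient")
  }
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  mat - (mat %*% Q) %*% t(Q)
}

#' Association statistics for residualized expression and genotype vectors
#'
#' The additive linear-model statistics on covariate-residualized vectors
#' (Frisch-Waugh: identical to the full model's genotype coefficient).
#' With \code{r = cor(e, g)}: \code{t = r * sqrt(df / (1 - r^2))},
#' \code{beta = r * sd(e) / sd(g)} (expression units per allele copy),
#' \code{se = |beta / t|}, two-sided Student-t p, explained variance
#' \code{t^2 / (t^2 + df)}, and a 95 percent confidence interval
#' \code{beta +/- t_crit(0.975, df) * se}.
#'
#' @param eResid,gResid residualized expression and dosage vectors.
#' @param df residual degrees of freedom
#'   (n_effective - covariates incl. intercept - 1).
#' @return list with \code{beta}, \code{se}, \code{t}, \code{p},
#'   \code{var_explained}, \code{ci95_low}, \code{ci95_high}. Zero genotype
#'   variance yields \code{p = NA} (flagged, excluded downstream).
#' @export
assocStats <- function(eResid, gResid, df) {
  if (df < 1) stop("df must be >= 1")
  eNorm <- sqrt(sum(eResid^2))
  gNorm <- sqrt(sum(gResid^2))
  if (gNorm == 0) {
    return(list(beta = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
                var_explained = NA_real_, ci95_low = NA_real_,
                ci95_high = NA_real_))
  }
  r <- if (eNorm == 0) 0 else sum(eResid * gResid) / (eNorm * gNorm)
  oneMinusR2 <- max(1 - r^2, .Machine$double.eps)
  tStat <- r * sqrt(df / oneMinusR2)
  beta <- sum(eResid * gResid) / gNorm^2
  se <- (eNorm / gNorm) * sqrt(oneMinusR2 / df)
  p <- 2 * pt(abs(tStat), df, lower.tail = FALSE)
  crit <- qt(0.975, df)
  list(beta = beta, se = se, t = tStat, p = p,
       var_explained = tStat^2 / (tStat^2 + df),
       ci95_low = beta - crit * se, ci95_high = beta + crit * se)
}

#' Classify SNP-gene pairs as cis or trans
#'
#' Distance is 0 when the SNP lies inside the gene body, otherwise the
#' base-pair distance to the nearer gene edge
#' (\code{min(|pos - start|, |pos - end|)}). A pair is cis when SNP and gene
#' share a chromosome and the distance is at most \code{cisWindow}
#' (inclusive), trans otherwise. All coordinates are 1-based.
#'
#' @param snpChrom,snpPos SNP coordinates (vectors).
#' @param geneChrom,geneStart,geneEnd gene coordinates (vectors, recycled
#'   against the SNP vectors).
#' @param cisWindow window in bp (default 100000).
#' @return data.frame with columns \code{class} ("cis"/"trans") and
#'   \code{distance} (bp).
#' @export
classifyPairs <- function(snpChrom, snpPos, geneChrom, geneStart, geneEnd,
                          cisWindow = 100000) {
  distance <- positionGeneDistance(snpPos, geneStart, geneEnd)
  cls <- ifelse(as.character(snpChrom) == as.character(geneChrom) &
                  distance <= cisWindow, "cis", "trans")
  data.frame(class = cls, distance = distance, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR against a fixed test total
#'
#' \code{q_i = min over j with p_j >= p_i of (mTotal * p_j / rank_j)},
#' capped at 1 -- the Matrix-eQTL convention in which only the smallest
#' p-values of a class are materialized but the correction uses the full
#' number of tests \code{mTotal} performed in that class.
#'
#' @param p p-values (the smallest \code{length(p)} of the class).
#' @param mTotal total number of tests in the class
#'   (>= \code{length(p)}).
#' @return q-values, same length and order as \code{p}.
#' @export
bhFdr <- function(p, mTotal = length(p)) {
  if (mTotal < length(p)) {
    stop("parameter error: mTotal must be >= length(p)")
  }
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH", n = mTotal)
}

#' Scan all SNP-gene pairs with the additive dosage model
#'
#' Residualizes expression and dosages against the covariate design
#' (intercept + age), computes every pairwise correlation in matrix form,
#' converts to beta/SE/t/p, classifies each pair cis or trans at the config
#' window, emits records below the per-class emission p threshold
#' (\code{pCis}, \code{pTrans}), and attaches per-class Benjamini-Hochberg
#' FDR computed against the total number of tests in that class. SNPs with
#' missing calls are handled by pairwise deletion (per-SNP complete
#' samples, per-pair degrees of freedom). Zero-variance genotypes yield
#' \code{p = NA} and are never emitted, but still count in the class totals
#' so that \code{nCisTests + nTransTests = nSnps * nGenes}.
#'
#' @param expr genes x samples normalized expression matrix (rownames are
#'   gene ids present in \code{genes}).
#' @param geno a \linkS4class{GenotypeExperiment} on the same samples.
#' @param covariates data.frame with \code{sample_id} and \code{age}.
#' @param genes GRanges of gene models covering \code{rownames(expr)}.
#' @param config an \linkS4class{EQTLConfig}.
#' @return An \linkS4class{EQTLScanResult}.
#' @export
scanAssociations <- function(expr, geno, covariates, genes,
                             config = eqtlConfig()) {
  d <- dosage(geno)
  vi <- variantInfo(geno)
  samples <- colnames(expr)
  if (!setequal(samples, colnames(d)) ||
      !setequal(samples, covariates$sample_id)) {
    stop("alignment error: expression, genotype and covariate samples differ")
  }
  d <- d[, samples, drop = FALSE]
  age <- covariates$age[match(samples, covariates$sample_id)]
  gIdx <- match(rownames(expr), S4Vectors::mcols(genes)$gene_id)
  if (anyNA(gIdx)) {
    stop("alignment error: expression rows missing from gene models")
  }
  genes <- genes[gIdx]
  gChrom <- as.character(GenomicRanges::seqnames(genes))
  gStart <- GenomicRanges::start(genes)
  gEnd <- GenomicRanges::end(genes)
  geneIds <- S4Vectors::mcols(genes)$gene_id

  n <- length(samples)
  X <- cbind(intercept = 1, age = age)
  nG <- nrow(expr); nV <- nrow(d)

  E <- residualize(expr, X)
  eNorm <- sqrt(rowSums(E^2))
  Es <- E / ifelse(eNorm == 0, 1, eNorm)

  rMat <- matrix(NA_real_, nG, nV)
  dfVec <- rep(NA_real_, nV)
  gNormVec <- rep(NA_real_, nV)
  eNormMat <- NULL   # per-SNP expression norms differ under missingness

  complete <- rowSums(is.na(d)) == 0L
  if (any(complete)) {
    G <- residualize(d[complete, , drop = FALSE], X)
    gNorm <- sqrt(rowSums(G^2))
    Gs <- G / ifelse(gNorm == 0, 1, gNorm)
    R <- Es %*% t(Gs)
    R[, gNorm == 0] <- NA_real_
    rMat[, complete] <- R
    dfVec[complete] <- n - ncol(X) - 1L
    gNormVec[complete] <- gNorm
  }
  incomplete <- which(!complete)
  if (length(incomplete)) {
    eNormMat <- matrix(NA_real_, nG, nV)
    eNormMat[, complete] <- eNorm
    for (j in incomplete) {
      ok <- !is.na(d[j, ])
      nOk <- sum(ok)
      if (nOk < ncol(X) + 2L) next
      Xo <- X[ok, , drop = FALSE]
      g <- residualize(matrix(d[j, ok], nrow = 1), Xo)[1, ]
      gn <- sqrt(sum(g^2))
      dfVec[j] <- nOk - ncol(X) - 1L
      gNormVec[j] <- gn
      if (gn == 0) next
      Eo <- residualize(expr[, ok, drop = FALSE], Xo)
      en <- sqrt(rowSums(Eo^2))
      eNormMat[, j] <- en
      rMat[, j] <- (Eo %*% g) / (ifelse(en == 0, 1, en) * gn)
    }
  }

  # cis/trans partition over all pairs
  vChrom <- vi$chrom; vPos <- vi$pos
  distMat <- pmax(outer(gStart, vPos, "-"), outer(-gEnd, vPos, function(a, b) b + a), 0)
  cisMask <- outer(gChrom, vChrom, "==") & distMat <= config@cisWindow
  nCisTests <- sum(cisMask)
  nTransTests <- nG * nV - nCisTests

  dfMat <- matrix(dfVec, nG, nV, byrow = TRUE)
  oneMinusR2 <- pmax(1 - rMat^2, .Machine$double.eps)
  tMat <- rMat * sqrt(dfMat / oneMinusR2)
  pMat <- 2 * pt(abs(tMat), dfMat, lower.tail = FALSE)

  emit <- function(mask, pThresh, mTotal) {
    sel <- which(mask & !is.na(pMat) & pMat < pThresh)
    if (!length(sel)) {
      df0 <- as.data.frame(stats::setNames(
        rep(list(numeric(0)), length(assocRecordColumns())),
        assocRecordColumns()))
      df0$snp_id <- character(0); df0$gene_id <- character(0)
      df0$class <- character(0)
      return(df0[, assocRecordColumns()])
    }
    gi <- ((sel - 1L) %% nG) + 1L
    vj <- ((sel - 1L) %/% nG) + 1L
    r <- rMat[sel]; df <- dfMat[sel]; tS <- tMat[sel]; p <- pMat[sel]
    en <- if (is.null(eNormMat)) eNorm[gi] else eNormMat[sel]
    gn <- gNormVec[vj]
    beta <- r * en / gn
    se <- (en / gn) * sqrt(pmax(1 - r^2, .Machine$double.eps) / df)
    crit <- qt(0.975, df)
    out <- data.frame(
      snp_id = vi$snp_id[vj], gene_id = geneIds[gi],
      beta = beta, se = se, t = tS, p = p,
      fdr = NA_real_,
      class = if (identical(pThresh, config@pCis)) "cis" else "trans",
      distance = distMat[sel],
      var_explained = tS^2 / (tS^2 + df),
      ci95_low = beta - crit * se, ci95_high = beta + crit * se,
      stringsAsFactors = FALSE)
    out <- out[order(out$p, out$snp_id, out$gene_id), , drop = FALSE]
    # underflowed p (reported as computed) enters BH at the smallest
    # representable positive value
    out$fdr <- bhFdr(pmax(out$p, .Machine$double.xmin), mTotal)
    rownames(out) <- NULL
    out
  }
  cis <- emit(cisMask, config@pCis, nCisTests)
  cis$class <- rep("cis", nrow(cis))
  trans <- emit(!cisMask, config@pTrans, nTransTests)
  trans$class <- rep("trans", nrow(trans))

  new("EQTLScanResult", cis = cis, trans = trans,
      nCisTests = nCisTests, nTransTests = nTransTests, config = config)
}

#' Reduce significant cis records to one top SNP per gene
#'
#' Restricts to records with FDR at most \code{fdrMax}, then keeps per gene
#' the record with the lowest FDR; ties are broken by lowest p, then smaller
#' position, then lexicographic snp_id.
#'
#' @param cisRecords cis association data.frame (from
#'   \code{\link{cisAssociations}}).
#' @param fdrMax significance cutoff (default 0.05).
#' @return data.frame with one row per significant eGene.
#' @export
topPerGene <- function(cisRecords, fdrMax = 0.05) {
  sig <- cisRecords[cisRecords$fdr <= fdrMax, , drop = FALSE]
  if (!nrow(sig)) return(sig)
  pos <- as.numeric(sub("^.*:", "", sig$snp_id))
  ord <- order(sig$gene_id, sig$fdr, sig$p, pos, sig$snp_id)
  sig <- sig[ord, , drop = FALSE]
  out <- sig[!duplicated(sig$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Observed vs expected quantiles for a QQ plot
#'
#' Observed quantiles are sorted -log10 p-values; expected quantiles are
#' \code{-log10((i - 0.5) / m)} for ranks i = 1..m.
#'
#' @param p nonempty p-value vector.
#' @return data.frame with \code{expected} and \code{observed}, both in
#'   -log10 units, ordered from least to most significant.
#' @export
qqData <- function(p) {
  if (!length(p)) stop("qqData needs a nonempty p-value vector")
  m <- length(p)
  i <- seq_len(m)
  data.frame(expected = rev(-log10((i - 0.5) / m)),
             observed = rev(-log10(sort(p, decreasing = FALSE))))
}
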