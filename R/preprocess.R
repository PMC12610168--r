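#' @include AllClasses.R config.R
#' @importFrom stats median cor
NULL

#' Minor allele frequency from allele dosages
#'
#' \code{f = sum(dosage) / (2 * n_nonmissing)}; the MAF is
#' \code{min(f, 1 - f)}. Missing calls are excluded from the denominator.
#'
#' @param dosages a dosage vector (one SNP) or a variants x samples matrix.
#' @return numeric MAF, one value per SNP.
#' @examples
#' computeMaf(c(2, 2, 1, 0))  # ALT freq 5/8, MAF 0.375
#' @export
computeMaf <- function(dosages) {
  if (is.matrix(dosages)) {
    nn <- rowSums(!is.na(dosages))
    if (any(nn == 0)) stop("undefined MAF: SNP(s) with all calls missing")
    f <- rowSums(dosages, na.rm = TRUE) / (2 * nn)
  } else {
    nn <- sum(!is.na(dosages))
    if (nn == 0) stop("undefined MAF: all calls missing")
    f <- sum(dosages, na.rm = TRUE) / (2 * nn)
  }
  unname(pmin(f, 1 - f))
}

#' Filter variants on minor allele frequency
#'
#' Keeps SNPs with MAF strictly greater than \code{mafMin}; monomorphic SNPs
#' (MAF 0) are always dropped. The retained variants carry their empirical
#' MAF in \code{mcols(...)$maf}.
#'
#' @param geno a \linkS4class{GenotypeExperiment}.
#' @param mafMin frequency threshold (default 0.01, strict).
#' @return A filtered \linkS4class{GenotypeExperiment}.
#' @export
filterVariants <- function(geno, mafMin = 0.01) {
  maf <- computeMaf(dosage(geno))
  keep <- maf > mafMin & maf > 0
  out <- geno[keep, ]
  rr <- SummarizedExperiment::rowRanges(out)
  S4Vectors::mcols(rr)$maf <- maf[keep]
  SummarizedExperiment::rowRanges(out) <- rr
  out
}

#' Sliding-window LD pruning (indep-pairwise style)
#'
#' Within each window of \code{windowSnps} consecutive SNPs on a chromosome,
#' any pair with dosage r^2 at or above \code{r2Max} loses its
#' later-positioned member; the window advances by \code{stepSnps}. Passes
#' repeat until no further SNP is removed, so no retained pair within a
#' window of the pruned list has r^2 >= r2Max. r^2 is the squared Pearson
#' correlation of 0/1/2 dosage vectors, pairwise-complete over missing
#' calls.
#'
#' @param geno a \linkS4class{GenotypeExperiment}, variants sorted by
#'   (chrom, pos).
#' @param windowSnps window size in SNPs (>= 2).
#' @param stepSnps window step in SNPs.
#' @param r2Max pruning threshold.
#' @return Character vector of retained snp_ids.
#' @export
ldPrune <- function(geno, windowSnps = 50L, stepSnps = 5L, r2Max = 0.2) {
  if (windowSnps < 2L) stop("parameter error: windowSnps must be >= 2")
  d <- dosage(geno)
  vi <- variantInfo(geno)
  keep <- rep(TRUE, nrow(d))
  for (ch in unique(vi$chrom)) {
    idx <- which(vi$chrom == ch)
    idx <- idx[order(vi$pos[idx])]
    repeat {
      removed <- FALSE
      live <- idx[keep[idx]]
      if (length(live) < 2L) break
      starts <- seq(1L, length(live), by = stepSnps)
      for (s in starts) {
        win <- live[s:min(s + windowSnps - 1L, length(live))]
        if (length(win) < 2L) next
        cm <- suppressWarnings(
          cor(t(d[win, , drop = FALSE]), use = "pairwise.complete.obs"))^2
        cm[is.na(cm)] <- 0
        for (a in seq_len(length(win) - 1L)) {
          if (!keep[win[a]]) next
          for (b in (a + 1L):length(win)) {
            j <- win[b]
            if (!keep[j]) next
            if (cm[a, b] >= r2Max) {
              keep[j] <- FALSE   # drop the later-positioned SNP
              removed <- TRUE
            }
          }
        }
      }
      if (!removed) break
    }
  }
  vi$snp_id[keep]
}

# Distance from a position to a gene interval under the pipeline's
# convention: 0 inside [start, end], else bases to the nearer edge.
positionGeneDistance <- function(pos, start, end) {
  pmax(start - pos, pos - end, 0)
}

#' Restrict variants to those within or near expressed genes
#'
#' Keeps SNPs whose distance to the nearest retained gene is at most
#' \code{window} (inclusive); SNPs on chromosomes without genes are dropped.
#'
#' @param geno a \linkS4class{GenotypeExperiment}.
#' @param genes GRanges of (expressed) gene models.
#' @param window distance bound in bp (default: the cis window, 100 kb).
#' @return A filtered \linkS4class{GenotypeExperiment}.
#' @export
restrictNearGenes <- function(geno, genes, window = 100000) {
  vi <- variantInfo(geno)
  if (length(genes) == 0L) {
    warning("empty gene set: all variants dropped")
    return(geno[integer(0), ])
  }
  gChrom <- as.character(GenomicRanges::seqnames(genes))
  gStart <- GenomicRanges::start(genes)
  gEnd <- GenomicRanges::end(genes)
  keep <- vapply(seq_len(nrow(vi)), function(i) {
    same <- gChrom == vi$chrom[i]
    if (!any(same)) return(FALSE)
    min(positionGeneDistance(vi$pos[i], gStart[same], gEnd[same])) <= window
  }, logical(1))
  geno[keep, ]
}

#' Filter lowly expressed genes
#'
#' Drops genes whose total count is below \code{minTotal} or whose number of
#' zero-count samples is at least \code{zeroSampleLimit}. With the default
#' \code{NA} limit the study rule is rescaled to the cohort:
#' \code{ceiling(70/75 * n)} (70 at n = 75).
#'
#' @param counts genes x samples integer matrix.
#' @param minTotal minimum row sum (default 200; a row sum of 199 is
#'   dropped, 200 kept).
#' @param zeroSampleLimit zero-sample cutoff (inclusive).
#' @return The filtered count matrix.
#' @export
filterGenes <- function(counts, minTotal = 200, zeroSampleLimit = NA) {
  n <- ncol(counts)
  if (is.na(zeroSampleLimit)) zeroSampleLimit <- ceiling(70 / 75 * n)
  keep <- rowSums(counts) >= minTotal & rowSums(counts == 0) < zeroSampleLimit
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes of
#' \code{count / geometric mean of that gene across samples}; genes with a
#' zero count in any sample are excluded from the median. Identical to the
#' standard RNA-seq median-of-ratios estimator.
#'
#' @param counts genes x samples count matrix (>= 2 samples).
#' @return Numeric vector of size factors, one per sample.
#' @export
computeSizeFactors <- function(counts) {
  if (ncol(counts) < 2L) stop("need >= 2 samples for size factors")
  allPos <- rowSums(counts <= 0) == 0
  if (!any(allPos)) {
    stop("size-factor error: no gene with all-positive counts; ",
         "relax the gene filter or supply deeper libraries")
  }
  logGeo <- rowMeans(log(counts[allPos, , drop = FALSE]))
  apply(counts[allPos, , drop = FALSE], 2, function(cnts) {
    exp(median(log(cnts) - logGeo))
  })
}

#' Normalize counts: size-factor scaling plus log2
#'
#' \code{log2(count / sizeFactor + 1)}, with median-of-ratios size factors.
#' This is a variance-stabilizing stand-in: it removes library-size
#' differences and compresses the count-variance relationship, which is the
#' property the linear scan needs; it is not the full DESeq2 VST.
#'
#' @param counts genes x samples count matrix.
#' @return list with \code{expr} (normalized matrix) and
#'   \code{sizeFactors}.
#' @export
normalizeCounts <- function(counts) {
  sf <- computeSizeFactors(counts)
  expr <- log2(sweep(counts, 2, sf, "/") + 1)
  list(expr = expr, sizeFactors = sf)
}

#' Positional variant-context labels
#'
#' A minimal positional stand-in for effect annotation: labels each variant
#' \code{genic} (inside a gene; refined to \code{genic_exonic} /
#' \code{genic_intronic} when exon intervals are supplied), \code{upstream}
#' or \code{downstream} (within the given distance of a gene's 5' or 3' end,
#' strand-aware), or \code{intergenic}.
#'
#' @param geno a \linkS4class{GenotypeExperiment} (or a GRanges of variants).
#' @param genes GRanges of gene models (strand used for up/downstream).
#' @param upstreamBp,downstreamBp window sizes in bp.
#' @param exons optional GRanges of exon intervals.
#' @return Character vector of labels, one per variant.
#' @export
classifyVariantContext <- function(geno, genes, upstreamBp = 5000,
                                   downstreamBp = 5000, exons = NULL) {
  variants <- if (is(geno, "GenotypeExperiment")) {
    SummarizedExperiment::rowRanges(geno)
  } else geno
  vChrom <- as.character(GenomicRanges::seqnames(variants))
  vPos <- GenomicRanges::start(variants)
  gChrom <- as.character(GenomicRanges::seqnames(genes))
  gStart <- GenomicRanges::start(genes)
  gEnd <- GenomicRanges::end(genes)
  gPlus <- as.character(GenomicRanges::strand(genes)) != "-"
  eChrom <- if (!is.null(exons)) as.character(GenomicRanges::seqnames(exons))
  vapply(seq_along(variants), function(i) {
    p <- vPos[i]
    inGene <- which(gChrom == vChrom[i] & gStart <= p & p <= gEnd)
    if (length(inGene)) {
      if (is.null(exons)) return("genic")
      inExon <- any(eChrom == vChrom[i] &
                      GenomicRanges::start(exons) <= p &
                      p <= GenomicRanges::end(exons))
      return(if (inExon) "genic_exonic" else "genic_intronic")
    }
    upStart <- ifelse(gPlus, gStart - upstreamBp, gEnd + 1)
    upEnd <- ifelse(gPlus, gStart - 1, gEnd + upstreamBp)
    if (any(gChrom == vChrom[i] & upStart <= p & p <= upEnd)) {
      return("upstream")
    }
    dnStart <- ifelse(gPlus, gEnd + 1, gStart - downstreamBp)
    dnEnd <- ifelse(gPlus, gEnd + downstreamBp, gStart - 1)
    if (any(gChrom == vChrom[i] & dnStart <= p & p <= dnEnd)) {
      return("downstream")
    }
    "intergenic"
  }, character(1))
}

#' Run the full preprocessing stage
#'
#' Expression side: low-count gene filter then median-of-ratios
#' normalization. Genotype side: MAF filter, LD pruning, then restriction to
#' SNPs within the cis window of an expressed gene (in that order). Returns
#' a QC report counting survivors of each step.
#'
#' @param counts genes x samples count matrix.
#' @param geno a \linkS4class{GenotypeExperiment}.
#' @param genes GRanges of gene models.
#' @param config an \linkS4class{EQTLConfig}.
#' @return list with \code{expr} (normalized matrix), \code{geno} (filtered
#'   genotypes), \code{genes} (expressed subset, scan order),
#'   \code{sizeFactors}, and \code{qc} (data.frame of step counts).
#' @export
preprocessStudy <- function(counts, geno, genes, config = eqtlConfig()) {
  qc <- list()
  qc[["genes_input"]] <- nrow(counts)
  zl <- effectiveZeroLimit(config, ncol(counts))
  kept <- filterGenes(counts, config@minGeneTotal, zl)
  qc[["genes_expressed"]] <- nrow(kept)
  norm <- normalizeCounts(kept)
  geneIds <- S4Vectors::mcols(genes)$gene_id
  expressed <- genes[match(rownames(kept), geneIds)]
  qc[["variants_input"]] <- nrow(dosage(geno))
  g1 <- filterVariants(geno, config@mafMin)
  qc[["variants_maf"]] <- nrow(dosage(g1))
  keepIds <- ldPrune(g1, config@ldWindowSnps, config@ldStepSnps,
                     config@ldR2Max)
  g2 <- g1[variantInfo(g1)$snp_id %in% keepIds, ]
  qc[["variants_ld_pruned"]] <- nrow(dosage(g2))
  g3 <- restrictNearGenes(g2, expressed, config@cisWindow)
  qc[["variants_near_genes"]] <- nrow(dosage(g3))
  list(expr = norm$expr, geno = g3, genes = expressed,
       sizeFactors = norm$sizeFactors,
       qc = data.frame(step = names(qc), count = unlist(qc),
                       row.names = NULL, stringsAsFactors = FALSE))
}
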