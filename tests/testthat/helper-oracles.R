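# Independent oracles and small fixture builders used across the suite.

# Per-pair OLS oracle: lm(expression ~ dosage + age). Returns the genotype
# coefficient's beta/se/t/p straight from summary.lm.
lmOracle <- function(e, g, age) {
  fit <- summary(lm(e ~ g + age))
  co <- fit$coefficients["g", ]
  list(beta = unname(co[1]), se = unname(co[2]), t = unname(co[3]),
       p = unname(co[4]), df = fit$df[2])
}

# Brute-force Benjamini-Hochberg per its definition: q_i = min over j with
# p_j >= p_i of (m / rank_j) * p_j, capped at 1.
bruteBH <- function(p, m = length(p)) {
  r <- rank(p, ties.method = "max")
  vapply(seq_along(p), function(i) {
    j <- which(p >= p[i])
    min(1, min((m / r[j]) * p[j]))
  }, numeric(1))
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, n) draws.
enumHyper <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- combn(N, n)
  hits <- colSums(draws <= K)   # genes 1..K form the term
  mean(hits >= k)
}

# Brute-force within-window r^2 violation check over a retained SNP list:
# windows of `windowSnps` consecutive retained SNPs per chromosome.
anyWindowViolation <- function(dosage, chrom, pos, retained, windowSnps,
                               r2Max) {
  for (ch in unique(chrom[retained])) {
    idx <- which(retained & chrom == ch)
    idx <- idx[order(pos[idx])]
    if (length(idx) < 2L) next
    for (a in seq_len(length(idx) - 1L)) {
      for (b in (a + 1L):min(a + windowSnps - 1L, length(idx))) {
        x <- dosage[idx[a], ]; y <- dosage[idx[b], ]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
        if (cor(x[ok], y[ok])^2 >= r2Max) return(TRUE)
      }
    }
  }
  FALSE
}

# GRanges builders for hand-made fixtures.
makeGenesGR <- function(chrom, start, end, strand = "+",
                        gene_id = sprintf("G%03d", seq_along(chrom)),
                        symbol = gene_id) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = rep_len(strand, length(chrom)))
  S4Vectors::mcols(gr)$gene_id <- gene_id
  S4Vectors::mcols(gr)$symbol <- symbol
  names(gr) <- gene_id
  gr
}

makeVariantsGR <- function(chrom, pos) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  S4Vectors::mcols(gr)$snp_id <- paste0(chrom, ":", pos)
  S4Vectors::mcols(gr)$ref <- rep("A", length(pos))
  S4Vectors::mcols(gr)$alt <- rep("G", length(pos))
  names(gr) <- S4Vectors::mcols(gr)$snp_id
  gr
}

makeGenoFromMatrix <- function(dosageMatrix, chrom = NULL, pos = NULL) {
  nv <- nrow(dosageMatrix)
  if (is.null(chrom)) chrom <- rep("1", nv)
  if (is.null(pos)) pos <- seq_len(nv) * 1000L
  if (is.null(colnames(dosageMatrix))) {
    colnames(dosageMatrix) <- sprintf("S%03d", seq_len(ncol(dosageMatrix)))
  }
  GenotypeExperiment(makeVariantsGR(chrom, pos), dosageMatrix)
}

# Minimal 3-variant VCF fixture text.
writeTinyVcf <- function(path, gts = NULL) {
  if (is.null(gts)) {
    gts <- rbind(c("0/0", "0/1", "1/1"),
                 c("0/1", "./.", "0/0"),
                 c("1/1", "1/1", "0/1"))
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "SA", "SB", "SC"), collapse = "\t"),
    paste(c("1", "101", "1:101", "A", "G", ".", "PASS", ".", "GT", gts[1, ]),
          collapse = "\t"),
    paste(c("1", "205", "1:205", "C", "T", ".", "PASS", ".", "GT", gts[2, ]),
          collapse = "\t"),
    paste(c("1", "999", "1:999", "G", "A", ".", "PASS", ".", "GT", gts[3, ]),
          collapse = "\t"))
  writeLines(lines, path)
  path
}

# A small complete study for scan-level tests: latent expression consumed
# directly (no count noise).
makeLatentStudy <- function(seed, nGenes = 20L, nSnps = 100L, nSamples = 75L,
                            nChrom = 1L, chromLen = 5e6,
                            mafLow = 0.1, mafHigh = 0.5,
                            hotspotSpec = list(), transSingletons = 0L,
                            sharedHub = FALSE, ...) {
  simulateStudy(nSamples = nSamples, nChrom = nChrom, chromLen = chromLen,
                nGenes = nGenes, nSnps = nSnps, mafLow = mafLow,
                mafHigh = mafHigh, hotspotSpec = hotspotSpec,
                transSingletons = transSingletons, sharedHub = sharedHub,
                counts = FALSE, seed = seed, ...)
}
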