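test_that("MAF is the folded ALT-allele frequency over non-missing calls", {
  # 75 samples carrying 11 ALT alleles total
  d <- c(rep(1, 11), rep(0, 64))
  expect_equal(computeMaf(d), 11 / 150)
  expect_equal(round(computeMaf(d), 6), 0.073333)
  expect_equal(computeMaf(rep(0, 10)), 0)
  expect_equal(computeMaf(c(2, 2, 1, 0)), 0.375)   # ALT freq 5/8 folded
  expect_equal(computeMaf(c(2, 2, NA, 0)), 1 / 3)  # NA out of the denominator
  expect_error(computeMaf(c(NA_real_, NA_real_)), "all calls missing")
})

test_that("variant filter is strict at the MAF threshold and drops monomorphics", {
  # mafs 0, .005, .01, .02, .3 over 100 samples
  mk <- function(nAlt) c(rep(1, nAlt), rep(0, 100 - nAlt))
  d <- rbind(mk(0), mk(1), mk(2), mk(4), mk(60))
  geno <- makeGenoFromMatrix(d)
  kept <- filterVariants(geno, mafMin = 0.01)
  expect_equal(nrow(dosage(kept)), 2L)   # only .02 and .3 survive (strict >)
  expect_equal(sort(variantInfo(kept)$maf), c(0.02, 0.3))
  # idempotent: refiltering the output changes nothing
  again <- filterVariants(kept, mafMin = 0.01)
  expect_identical(dosage(again), dosage(kept))
})

test_that("LD pruning keeps one SNP per perfect block and spares uncorrelated SNPs", {
  set.seed(42)
  base <- rbinom(80, 2, 0.4)
  # two identical columns -> exactly one retained
  g1 <- makeGenoFromMatrix(rbind(base, base))
  expect_equal(ldPrune(g1, windowSnps = 10L, stepSnps = 2L), "1:1000")

  # three mutually uncorrelated SNPs -> all retained
  d3 <- rbind(rbinom(80, 2, 0.4), rbinom(80, 2, 0.4), rbinom(80, 2, 0.4))
  while (max(cor(t(d3))[upper.tri(diag(3))]^2) >= 0.2) {
    d3 <- rbind(rbinom(80, 2, 0.4), rbinom(80, 2, 0.4), rbinom(80, 2, 0.4))
  }
  g3 <- makeGenoFromMatrix(d3)
  expect_equal(length(ldPrune(g3, windowSnps = 10L, stepSnps = 2L)), 3L)

  # 10-SNP zero-flip blocks: exactly one survivor per block
  sc <- simulateGenome(nChrom = 1L, chromLen = 1e6, nGenes = 2L, nSnps = 30L,
                       guaranteeCisSnp = FALSE, seed = 3L)
  gb <- simulateGenotypes(sc$variants, 60L, mafLow = 0.3, mafHigh = 0.4,
                          ldBlock = 10L, flipProb = 0, seed = 3L)
  keep <- ldPrune(gb, windowSnps = 15L, stepSnps = 3L)
  expect_equal(length(keep), 3L)
  expect_error(ldPrune(g1, windowSnps = 1L), "parameter")
})

test_that("pruned panels contain no retained within-window pair at or above r2Max", {
  for (seed in 1:5) {
    sc <- simulateGenome(nChrom = 2L, chromLen = 2e6, nGenes = 4L,
                         nSnps = 80L, guaranteeCisSnp = FALSE, seed = seed)
    geno <- simulateGenotypes(sc$variants, 60L, mafLow = 0.1, mafHigh = 0.5,
                              ldBlock = 5L, flipProb = 0.05, seed = seed)
    keep <- ldPrune(geno, windowSnps = 20L, stepSnps = 5L, r2Max = 0.2)
    vi <- variantInfo(geno)
    retained <- vi$snp_id %in% keep
    expect_false(anyWindowViolation(dosage(geno), vi$chrom, vi$pos,
                                    retained, 20L, 0.2))
  }
})

test_that("near-gene restriction is inclusive at the window bound", {
  genes <- makeGenesGR("1", 500000L, 600000L)
  pos <- c(550000L,          # inside: distance 0
           700000L,          # 100,000 past the end: retained (inclusive)
           700001L,          # 100,001: dropped
           399999L)          # 100,001 before start: dropped
  d <- matrix(rep(c(0, 1, 2, 1), 4), nrow = 4, byrow = TRUE)
  geno <- makeGenoFromMatrix(d, chrom = rep("1", 4), pos = pos)
  kept <- restrictNearGenes(geno, genes, window = 100000)
  expect_equal(variantInfo(kept)$pos, c(550000L, 700000L))
  # SNP on a chromosome without genes is dropped
  g2 <- makeGenoFromMatrix(matrix(c(0, 1, 2), 1), chrom = "2", pos = 10L)
  expect_equal(nrow(dosage(restrictNearGenes(g2, genes))), 0L)
  expect_warning(restrictNearGenes(geno, genes[0]), "empty gene set")
})

test_that("gene filter applies the verbatim count and zero-sample rules", {
  n <- 75
  mk <- function(total, nZero) {
    pos <- n - nZero
    c(rep(round(total / pos), pos - 1),
      total - round(total / pos) * (pos - 1), rep(0, nZero))
  }
  counts <- rbind(
    sum199 = mk(199, 0),
    sum200 = mk(200, 0),
    zeros70 = mk(5000, 70),
    zeros69 = mk(5000, 69),
    healthy = rep(140, n))
  colnames(counts) <- sprintf("S%03d", 1:n)
  kept <- filterGenes(counts)
  expect_identical(rownames(kept), c("sum200", "zeros69", "healthy"))
})

test_that("median-of-ratios size factors match the hand calculation and DESeq2", {
  # 3x3 toy: per-gene geometric means, per-sample median ratio
  counts <- matrix(c(100, 200, 400,
                     10,  20,  40,
                     50,  50,  50), nrow = 3, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"), c("a", "b", "c")))
  geo <- exp(rowMeans(log(counts)))
  expected <- apply(counts / geo, 2, median)
  expect_equal(computeSizeFactors(counts), expected, tolerance = 1e-12)
  ds2 <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(computeSizeFactors(counts)), unname(ds2),
               tolerance = 1e-12)

  # size factors are defined up to a common scale: doubling one sample's
  # counts doubles its factor relative to the others, and normalized values
  # are invariant up to a global additive constant (and the +1 offset,
  # negligible at large counts)
  big <- counts * 1000
  doubled <- big; doubled[, 2] <- doubled[, 2] * 2
  sfB <- computeSizeFactors(big); sfD <- computeSizeFactors(doubled)
  expect_equal(unname((sfD[2] / sfD[1]) / (sfB[2] / sfB[1])), 2,
               tolerance = 1e-12)
  shift <- normalizeCounts(doubled)$expr - normalizeCounts(big)$expr
  expect_lt(diff(range(shift)), 1e-3)

  # all-zero-containing genes cannot anchor size factors
  zeroy <- matrix(c(0, 5, 3, 0), 2)
  expect_error(computeSizeFactors(zeroy), "all-positive")
})

test_that("variant context labels are positional and strand-aware", {
  genes <- makeGenesGR(c("1", "1"), c(10000L, 50000L), c(20000L, 60000L),
                       strand = c("+", "-"))
  pos <- c(15000L,   # inside gene
           9000L,    # 1 kb 5' of + gene start -> upstream
           21000L,   # 3' of + gene -> downstream
           61000L,   # 5' of - gene (past end) -> upstream
           500000L)  # far away -> intergenic
  geno <- makeGenoFromMatrix(matrix(1, 5, 3), chrom = rep("1", 5), pos = pos)
  labels <- classifyVariantContext(geno, genes, upstreamBp = 5000,
                                   downstreamBp = 5000)
  expect_equal(labels, c("genic", "upstream", "downstream", "upstream",
                         "intergenic"))
  # exon refinement
  exons <- GenomicRanges::GRanges("1", IRanges::IRanges(14000L, 16000L))
  labEx <- classifyVariantContext(geno, genes, exons = exons)
  expect_equal(labEx[1], "genic_exonic")
  geno2 <- makeGenoFromMatrix(matrix(1, 1, 3), chrom = "1", pos = 18000L)
  expect_equal(classifyVariantContext(geno2, genes, exons = exons),
               "genic_intronic")
})

test_that("each genotype QC step is idempotent at its own stage", {
  study <- simulateStudy(nSamples = 30L, nChrom = 2L, nGenes = 40L,
                         nSnps = 150L, cisFraction = 0.2,
                         hotspotSpec = list(), transSingletons = 0L,
                         sharedHub = FALSE, seed = 17L)
  cfg <- eqtlConfig()
  # MAF filter
  g1 <- filterVariants(study$geno, cfg@mafMin)
  expect_identical(dosage(filterVariants(g1, cfg@mafMin)), dosage(g1))
  # LD pruning: re-pruning the pruned panel removes nothing
  keep1 <- ldPrune(g1, cfg@ldWindowSnps, cfg@ldStepSnps, cfg@ldR2Max)
  g2 <- g1[variantInfo(g1)$snp_id %in% keep1, ]
  keep2 <- ldPrune(g2, cfg@ldWindowSnps, cfg@ldStepSnps, cfg@ldR2Max)
  expect_identical(sort(keep2), sort(keep1))
  # near-gene restriction
  g3 <- restrictNearGenes(g2, study$genes, cfg@cisWindow)
  g3b <- restrictNearGenes(g3, study$genes, cfg@cisWindow)
  expect_identical(dosage(g3b), dosage(g3))
  # gene filter
  kept <- filterGenes(study$counts, cfg@minGeneTotal, 28)
  expect_identical(filterGenes(kept, cfg@minGeneTotal, 28), kept)
  # QC report counts are monotone non-increasing along the chain
  prep <- preprocessStudy(study$counts, study$geno, study$genes, cfg)
  qcv <- prep$qc$count[prep$qc$step %in%
    c("variants_input", "variants_maf", "variants_ld_pruned",
      "variants_near_genes")]
  expect_true(all(diff(qcv) <= 0))
})
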