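test_that("residualization projects onto the covariate complement", {
  set.seed(1)
  n <- 5
  X <- cbind(1, age = c(10, 14, 20, 8, 30))
  m <- matrix(rnorm(3 * n), 3, n)
  r <- residualize(m, X)
  # residual rows orthogonal to every covariate column
  expect_lt(max(abs(r %*% X)), 1e-10)
  # intercept only -> mean centering
  r0 <- residualize(m, matrix(1, n, 1))
  expect_equal(r0, m - rowMeans(m), tolerance = 1e-12)
  # projector idempotence
  expect_equal(residualize(r, X), r, tolerance = 1e-12)
  # matches explicit per-row OLS residuals
  for (i in 1:3) {
    expect_equal(unname(r[i, ]), unname(resid(lm(m[i, ] ~ X[, 2]))),
                 tolerance = 1e-12)
  }
  expect_error(residualize(m, cbind(1, c(2, 2, 2, 2, 2))), "collinearity")
})

test_that("association statistics match the per-pair OLS oracle", {
  set.seed(7)
  n <- 8
  age <- c(9, 12, 15, 20, 11, 25, 30, 14)
  g <- c(0, 1, 2, 1, 0, 2, 1, 0)
  e <- 0.8 * g + 0.05 * age + rnorm(n)
  X <- cbind(1, age)
  eR <- residualize(matrix(e, 1), X)[1, ]
  gR <- residualize(matrix(g, 1), X)[1, ]
  df <- n - 3
  st <- assocStats(eR, gR, df)
  or <- lmOracle(e, g, age)
  expect_equal(st$beta, or$beta, tolerance = 1e-10)
  expect_equal(st$se, or$se, tolerance = 1e-10)
  expect_equal(st$t, or$t, tolerance = 1e-10)
  expect_equal(st$p, or$p, tolerance = 1e-10)
  expect_equal(abs(st$t), abs(st$beta / st$se), tolerance = 1e-10)
  expect_equal(st$var_explained, st$t^2 / (st$t^2 + df), tolerance = 1e-12)
  ciOr <- confint(lm(e ~ g + age))["g", ]
  expect_equal(c(st$ci95_low, st$ci95_high), unname(ciOr), tolerance = 1e-10)

  # orthogonal vectors: beta 0, t 0, p 1
  st0 <- assocStats(c(1, -1, 0, 0), c(0, 0, 1, -1), 2)
  expect_equal(st0$beta, 0)
  expect_equal(st0$p, 1)

  # perfect correlation: underflow handled without crash, p >= 0 tiny
  stp <- assocStats(c(-3, -1, 1, 3), c(-3, -1, 1, 3) * 0.5, 2)
  expect_true(is.finite(stp$t))
  expect_true(stp$p >= 0)
  expect_lt(stp$p, 1e-12)

  # zero genotype variance flagged with NA p
  stz <- assocStats(c(1, -1, 0), c(0, 0, 0), 1)
  expect_true(is.na(stz$p))
})

test_that("cis/trans classification uses inclusive gene-body distance", {
  # inside the gene
  inside <- classifyPairs("21", 17035557, "21", 17000000, 17100000)
  expect_equal(inside$class, "cis")
  expect_equal(inside$distance, 0)
  # different chromosome: trans regardless of position
  other <- classifyPairs("1", 17035557, "21", 17000000, 17100000)
  expect_equal(other$class, "trans")
  # boundary: exactly 100,000 past the end is cis, one more is trans
  bound <- classifyPairs(c("5", "5"), c(17200000, 17200001),
                         "5", 17000000, 17100000, cisWindow = 100000)
  expect_equal(bound$class, c("cis", "trans"))
  expect_equal(bound$distance, c(100000, 100001))
  # symmetric on the upstream side
  up <- classifyPairs(c("5", "5"), c(16900000, 16899999),
                      "5", 17000000, 17100000)
  expect_equal(up$class, c("cis", "trans"))
})

test_that("BH against a fixed total matches the brute-force definition", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04), 4), rep(0.04, 4))
  expect_equal(bhFdr(0.5, 1), 0.5)
  set.seed(99)
  for (rep in 1:50) {
    len <- sample(1:200, 1)
    p <- runif(len)
    m <- len + sample(0:500, 1)
    q <- bhFdr(p, m)
    expect_equal(q, bruteBH(p, m), tolerance = 1e-14)
    # monotone in p
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bhFdr(c(0.1, 0.2), 1), "mTotal")
  expect_error(bhFdr(c(0, 0.2), 5), "p-values")
})

test_that("scan conserves the pair partition and matches per-pair lm", {
  study <- makeLatentStudy(5L, nGenes = 15L, nSnps = 60L, nSamples = 60L,
                           cisFraction = 0.4, cisBetaMean = 1, cisBetaSd = 0.5)
  cfg <- eqtlConfig()
  scan <- scanAssociations(study$latent, study$geno, study$covariates,
                           study$genes, cfg)
  tc <- testCounts(scan)
  expect_equal(unname(tc["cis"] + tc["trans"]),
               nrow(dosage(study$geno)) * nrow(study$latent))
  recs <- rbind(cisAssociations(scan), transAssociations(scan))
  expect_gt(nrow(recs), 0)
  d <- dosage(study$geno)
  age <- study$covariates$age
  for (i in seq_len(nrow(recs))) {
    e <- study$latent[recs$gene_id[i], ]
    g <- d[recs$snp_id[i], colnames(study$latent)]
    or <- lmOracle(e, g, age)
    expect_equal(recs$beta[i], or$beta, tolerance = 1e-8)
    expect_equal(recs$se[i], or$se, tolerance = 1e-8)
    expect_equal(recs$t[i], or$t, tolerance = 1e-8)
    expect_equal(recs$p[i], or$p, tolerance = 1e-8)
  }
  # emitted records respect the per-class emission thresholds
  expect_true(all(cisAssociations(scan)$p < cfg@pCis))
  expect_true(all(transAssociations(scan)$p < cfg@pTrans))
  expect_true(all(cisAssociations(scan)$class == "cis"))
})

test_that("missing genotype calls are handled by pairwise deletion", {
  study <- makeLatentStudy(8L, nGenes = 6L, nSnps = 20L, nSamples = 50L,
                           cisFraction = 0.5, cisBetaMean = 1.5,
                           cisBetaSd = 0)
  d <- dosage(study$geno)
  set.seed(8)
  holes <- matrix(runif(length(d)) < 0.06, nrow = nrow(d))
  d[holes] <- NA_real_
  genoNA <- GenotypeExperiment(
    SummarizedExperiment::rowRanges(study$geno), d)
  scan <- scanAssociations(study$latent, genoNA, study$covariates,
                           study$genes, eqtlConfig())
  recs <- rbind(cisAssociations(scan), transAssociations(scan))
  expect_gt(nrow(recs), 0)
  age <- study$covariates$age
  for (i in seq_len(nrow(recs))) {
    e <- study$latent[recs$gene_id[i], ]
    g <- d[recs$snp_id[i], colnames(study$latent)]
    ok <- !is.na(g)
    or <- lmOracle(e[ok], g[ok], age[ok])
    expect_equal(recs$beta[i], or$beta, tolerance = 1e-8)
    expect_equal(recs$p[i], or$p, tolerance = 1e-8)
  }
})

test_that("zero-variance genotypes are excluded but still counted", {
  study <- makeLatentStudy(9L, nGenes = 5L, nSnps = 12L, nSamples = 40L,
                           cisFraction = 0)
  d <- dosage(study$geno)
  d[3, ] <- 1   # monomorphic
  genoZ <- GenotypeExperiment(SummarizedExperiment::rowRanges(study$geno), d)
  scan <- scanAssociations(study$latent, genoZ, study$covariates,
                           study$genes, eqtlConfig(pCis = 1))
  tc <- testCounts(scan)
  expect_equal(unname(tc["cis"] + tc["trans"]), nrow(d) * 5)
  zId <- variantInfo(genoZ)$snp_id[3]
  expect_false(zId %in% cisAssociations(scan)$snp_id)
  expect_false(zId %in% transAssociations(scan)$snp_id)
})

test_that("sample misalignment raises an alignment error", {
  study <- makeLatentStudy(10L, nGenes = 4L, nSnps = 10L, nSamples = 20L)
  badCov <- study$covariates
  badCov$sample_id[1] <- "NOT_A_SAMPLE"
  expect_error(
    scanAssociations(study$latent, study$geno, badCov, study$genes,
                     eqtlConfig()),
    "alignment")
})

test_that("top-per-gene reduction applies the FDR cut and the tie-break order", {
  rec <- function(snp, gene, p, fdr) {
    data.frame(snp_id = snp, gene_id = gene, beta = 1, se = 1, t = 1, p = p,
               fdr = fdr, class = "cis", distance = 0, var_explained = 0.1,
               ci95_low = 0, ci95_high = 2, stringsAsFactors = FALSE)
  }
  recs <- rbind(
    rec("1:500", "GA", 0.001, 0.01),
    rec("1:100", "GA", 0.002, 0.02),   # worse fdr: dropped
    rec("1:200", "GB", 0.003, 0.03),
    rec("1:100", "GB", 0.003, 0.03),   # tie on fdr+p: smaller pos wins
    rec("1:900", "GC", 0.5, 0.50))     # above fdrMax: gene absent
  top <- topPerGene(recs, fdrMax = 0.05)
  expect_equal(nrow(top), 2L)
  expect_equal(top$snp_id[top$gene_id == "GA"], "1:500")
  expect_equal(top$snp_id[top$gene_id == "GB"], "1:100")
  expect_false("GC" %in% top$gene_id)
})

test_that("QQ quantiles follow the (i - 0.5)/m convention", {
  q <- qqData(c(0.125, 0.375, 0.625, 0.875))
  expect_equal(q$observed, q$expected, tolerance = 1e-12)
  # uniform grid hugs the diagonal; a spike stands off it
  grid <- (1:100) / 100
  qg <- qqData(grid)
  expect_lt(max(abs(qg$observed - qg$expected)), 0.35)
  qs <- qqData(c(1e-12, grid))
  expect_gt(max(qs$observed - qs$expected), 5)
  expect_error(qqData(numeric(0)), "nonempty")
})
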