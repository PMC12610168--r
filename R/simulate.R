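#' @include AllClasses.R config.R io.R
#' @importFrom stats rnorm runif rbinom rnbinom
NULL

#' Simulate slaughter ages
#'
#' Ages (months) drawn from a normal distribution truncated at 1 month. The
#' defaults (mean 14.3, sd 8.8) are the cohort this pipeline emulates: 75
#' steers sampled across growing-to-late-fattening stages.
#'
#' @param n number of animals.
#' @param meanAge,sdAge normal parameters in months.
#' @param minAge truncation point (months).
#' @param seed optional integer seed.
#' @return data.frame with columns \code{sample_id}, \code{age}.
#' @export
simulateAges <- function(n, meanAge = 14.3, sdAge = 8.8, minAge = 1,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  age <- numeric(0)
  while (length(age) < n) {
    draw <- rnorm(n, meanAge, sdAge)
    age <- c(age, draw[draw >= minAge])
  }
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             age = age[seq_len(n)], stringsAsFactors = FALSE)
}

#' Simulate a genome scaffold: gene models and SNP positions
#'
#' Places non-overlapping gene intervals on \code{nChrom} chromosomes (one
#' gene per equal-width slot, at a random offset) and uniform SNP positions.
#' With \code{guaranteeCisSnp} every gene additionally receives one SNP
#' inside its body, so the cis window always has at least one candidate.
#'
#' @param nChrom number of chromosomes.
#' @param chromLen chromosome length in bp (recycled).
#' @param nGenes,nSnps totals across the genome.
#' @param geneLenRange min/max gene length in bp.
#' @param guaranteeCisSnp logical; plant one SNP inside every gene.
#' @param seed optional integer seed.
#' @return list with \code{genes} (GRanges: gene_id, symbol) and
#'   \code{variants} (width-1 GRanges: snp_id, ref, alt).
#' @export
simulateGenome <- function(nChrom = 5L, chromLen = 2e7, nGenes = 300L,
                           nSnps = 1500L, geneLenRange = c(5000, 30000),
                           guaranteeCisSnp = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chromLen <- rep_len(chromLen, nChrom)
  chroms <- as.character(seq_len(nChrom))
  genesPerChrom <- diff(floor(seq(0, nGenes, length.out = nChrom + 1)))
  rows <- list()
  for (i in seq_len(nChrom)) {
    ng <- genesPerChrom[i]
    if (ng == 0L) next
    slot <- floor(chromLen[i] / ng)
    if (slot < geneLenRange[2] + 2L) {
      stop("capacity error: cannot pack ", ng, " genes of up to ",
           geneLenRange[2], " bp into chromosome ", chroms[i])
    }
    len <- round(runif(ng, geneLenRange[1], geneLenRange[2]))
    offset <- floor(runif(ng, 1, slot - len))
    start <- (seq_len(ng) - 1L) * slot + offset
    rows[[i]] <- data.frame(chrom = chroms[i], start = start,
                            end = start + len - 1L,
                            stringsAsFactors = FALSE)
  }
  gdf <- do.call(rbind, rows)
  gdf$strand <- sample(c("+", "-"), nrow(gdf), replace = TRUE)
  gdf$gene_id <- sprintf("G%04d", seq_len(nrow(gdf)))
  gdf$symbol <- sprintf("SYM%d", seq_len(nrow(gdf)))
  genes <- GenomicRanges::GRanges(
    seqnames = factor(gdf$chrom, levels = chroms),
    ranges = IRanges::IRanges(gdf$start, gdf$end),
    strand = gdf$strand)
  S4Vectors::mcols(genes)$gene_id <- gdf$gene_id
  S4Vectors::mcols(genes)$symbol <- gdf$symbol
  names(genes) <- gdf$gene_id

  snpsPerChrom <- diff(floor(seq(0, nSnps, length.out = nChrom + 1)))
  vchrom <- rep(chroms, snpsPerChrom)
  vpos <- unlist(lapply(seq_len(nChrom), function(i) {
    sort(sample.int(chromLen[i], snpsPerChrom[i]))
  }))
  if (guaranteeCisSnp) {
    inside <- floor(runif(nrow(gdf), gdf$start, gdf$end + 1))
    vchrom <- c(vchrom, gdf$chrom)
    vpos <- c(vpos, inside)
  }
  ord <- order(match(vchrom, chroms), vpos)
  vchrom <- vchrom[ord]; vpos <- vpos[ord]
  dup <- duplicated(paste0(vchrom, ":", vpos))
  vchrom <- vchrom[!dup]; vpos <- vpos[!dup]
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(vpos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  variants <- GenomicRanges::GRanges(
    seqnames = factor(vchrom, levels = chroms),
    ranges = IRanges::IRanges(vpos, width = 1L))
  S4Vectors::mcols(variants)$snp_id <- paste0(vchrom, ":", vpos)
  S4Vectors::mcols(variants)$ref <- unname(ref)
  S4Vectors::mcols(variants)$alt <- unname(alt)
  names(variants) <- S4Vectors::mcols(variants)$snp_id
  list(genes = genes, variants = variants)
}

#' Simulate Hardy-Weinberg genotypes with optional LD blocks
#'
#' Each LD block (consecutive SNPs on a chromosome, block size
#' \code{ldBlock}) shares an allele frequency drawn uniformly from
#' \code{[mafLow, mafHigh]}. A block founder's alleles are Bernoulli draws at
#' that frequency (Hardy-Weinberg); every member SNP copies each founder
#' allele with probability \code{1 - flipProb} and redraws it at the block
#' frequency otherwise, which preserves the marginal frequency while making
#' within-block r^2 high. \code{ldBlock = 1} gives independent SNPs.
#'
#' @param variants width-1 GRanges from \code{\link{simulateGenome}}.
#' @param nSamples number of diploid samples (>= 2).
#' @param mafLow,mafHigh allele-frequency range, 0 < low <= high <= 0.5.
#' @param ldBlock block size in SNPs.
#' @param flipProb per-allele redraw probability within a block.
#' @param missingRate fraction of calls set to missing.
#' @param seed optional integer seed.
#' @return A \linkS4class{GenotypeExperiment}.
#' @export
simulateGenotypes <- function(variants, nSamples, mafLow = 0.05,
                              mafHigh = 0.5, ldBlock = 1L, flipProb = 0.1,
                              missingRate = 0, seed = NULL) {
  if (nSamples < 2L) stop("size error: nSamples must be >= 2")
  stopifnot(mafLow > 0, mafLow <= mafHigh, mafHigh <= 0.5)
  if (!is.null(seed)) set.seed(seed)
  nv <- length(variants)
  chrom <- as.character(GenomicRanges::seqnames(variants))
  dos <- matrix(NA_real_, nrow = nv, ncol = nSamples)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    blocks <- split(idx, ceiling(seq_along(idx) / ldBlock))
    for (b in blocks) {
      p <- runif(1, mafLow, mafHigh)
      founder1 <- rbinom(nSamples, 1L, p)
      founder2 <- rbinom(nSamples, 1L, p)
      for (j in b) {
        flip1 <- rbinom(nSamples, 1L, flipProb) == 1L
        flip2 <- rbinom(nSamples, 1L, flipProb) == 1L
        a1 <- ifelse(flip1, rbinom(nSamples, 1L, p), founder1)
        a2 <- ifelse(flip2, rbinom(nSamples, 1L, p), founder2)
        dos[j, ] <- a1 + a2
      }
    }
  }
  colnames(dos) <- sprintf("S%03d", seq_len(nSamples))
  if (missingRate > 0) {
    dos[matrix(runif(length(dos)) < missingRate, nrow = nv)] <- NA_real_
  }
  GenotypeExperiment(variants, dos)
}

#' Plant cis effects, trans hub SNPs, and singleton trans effects
#'
#' Produces the generator's effect ledger: each record is a (SNP, gene) pair
#' with a mode (\code{additive}: the effect scales with allele dosage;
#' \code{het_peak}: the effect applies only to heterozygotes, the
#' overdominance pattern), an effect size \code{beta} in latent-expression
#' standard deviations per allele copy, and a class. Cis records always lie
#' within \code{cisWindow} of their gene; trans hub targets and singleton
#' targets are always beyond it (or on another chromosome).
#'
#' @param genes,variants GRanges from \code{\link{simulateGenome}}.
#' @param cisWindow cis window in bp.
#' @param cisFraction fraction of genes given one cis effect.
#' @param cisBetaMean,cisBetaSd normal parameters for cis effect sizes.
#' @param hotspotSpec list of \code{c(nTargets, betaSd)} pairs; each plants
#'   one master-regulator SNP with that many distant targets, effect sizes
#'   drawn N(0, betaSd^2).
#' @param transSingletons number of additional one-target trans effects
#'   (background for the per-SNP regulated-gene count distribution).
#' @param singletonBetaSd effect-size sd for singleton trans effects.
#' @param mode effect mode for the planted cis records.
#' @param sharedHub logical; give the first hub SNP a cis record on its
#'   nearest gene as well, emulating a shared cis+trans regulatory hub.
#' @param sharedHubCisBeta magnitude of the shared hub's cis effect (sign
#'   random). The default 3 makes the hub a top-tier cis signal, the
#'   pattern a shared regulatory hub shows in real cohorts.
#' @param seed optional integer seed.
#' @return data.frame with columns \code{snp_id, gene_id, mode, beta, class}.
#' @export
plantEffects <- function(genes, variants, cisWindow = 100000,
                         cisFraction = 0.25, cisBetaMean = 0,
                         cisBetaSd = 1.5, hotspotSpec = list(),
                         transSingletons = 0L, singletonBetaSd = 1.5,
                         mode = c("additive", "het_peak"),
                         sharedHub = FALSE, sharedHubCisBeta = 3,
                         seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(cisFraction >= 0, cisFraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  vChrom <- as.character(GenomicRanges::seqnames(variants))
  vPos <- GenomicRanges::start(variants)
  vId <- S4Vectors::mcols(variants)$snp_id
  gChrom <- as.character(GenomicRanges::seqnames(genes))
  gStart <- GenomicRanges::start(genes)
  gEnd <- GenomicRanges::end(genes)
  gId <- S4Vectors::mcols(genes)$gene_id

  cisSnpsOf <- function(gi) {
    same <- which(vChrom == gChrom[gi])
    d <- pmax(gStart[gi] - vPos[same], vPos[same] - gEnd[gi], 0)
    same[d <= cisWindow]
  }
  transGenesOf <- function(vj) {
    d <- pmax(gStart - vPos[vj], vPos[vj] - gEnd, 0)
    which(gChrom != vChrom[vj] | d > cisWindow)
  }

  recs <- list()
  nCis <- round(cisFraction * length(genes))
  if (nCis > 0) {
    sel <- sort(sample.int(length(genes), nCis))
    for (gi in sel) {
      cand <- cisSnpsOf(gi)
      if (!length(cand)) {
        stop("planting error: no SNP within ", cisWindow, " bp of gene ",
             gId[gi])
      }
      vj <- if (length(cand) == 1L) cand else sample(cand, 1L)
      recs[[length(recs) + 1L]] <- data.frame(
        snp_id = vId[vj], gene_id = gId[gi], mode = mode,
        beta = rnorm(1, cisBetaMean, cisBetaSd), class = "cis",
        stringsAsFactors = FALSE)
    }
  }

  usedHubs <- integer(0)
  for (h in seq_along(hotspotSpec)) {
    spec <- hotspotSpec[[h]]
    nTargets <- as.integer(spec[1]); betaSd <- as.numeric(spec[2])
    pool <- setdiff(seq_along(variants), usedHubs)
    if (h == 1L && sharedHub) {
      # hub must be cis-eligible to at least one gene
      eligible <- pool[vapply(pool, function(vj) {
        any(gChrom == vChrom[vj] &
              pmax(gStart - vPos[vj], vPos[vj] - gEnd, 0) <= cisWindow)
      }, logical(1))]
      if (!length(eligible)) stop("planting error: no cis-eligible hub SNP")
      vj <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
      same <- which(gChrom == vChrom[vj])
      d <- pmax(gStart[same] - vPos[vj], vPos[vj] - gEnd[same], 0)
      gHost <- same[which.min(d)]
      recs[[length(recs) + 1L]] <- data.frame(
        snp_id = vId[vj], gene_id = gId[gHost], mode = "additive",
        beta = sample(c(-1, 1), 1L) * sharedHubCisBeta, class = "cis",
        stringsAsFactors = FALSE)
    } else {
      vj <- if (length(pool) == 1L) pool else sample(pool, 1L)
    }
    usedHubs <- c(usedHubs, vj)
    targets <- transGenesOf(vj)
    if (length(targets) < nTargets) {
      stop("planting error: hub SNP ", vId[vj], " has only ",
           length(targets), " eligible distant genes (need ", nTargets, ")")
    }
    tg <- sample(targets, nTargets)
    recs[[length(recs) + 1L]] <- data.frame(
      snp_id = vId[vj], gene_id = gId[tg], mode = "additive",
      beta = rnorm(nTargets, 0, betaSd), class = "trans",
      stringsAsFactors = FALSE)
  }

  if (transSingletons > 0L) {
    pool <- setdiff(seq_along(variants), usedHubs)
    sjs <- sample(pool, transSingletons)
    for (vj in sjs) {
      targets <- transGenesOf(vj)
      if (!length(targets)) next
      tg <- if (length(targets) == 1L) targets else sample(targets, 1L)
      recs[[length(recs) + 1L]] <- data.frame(
        snp_id = vId[vj], gene_id = gId[tg], mode = "additive",
        beta = rnorm(1, 0, singletonBetaSd), class = "trans",
        stringsAsFactors = FALSE)
    }
  }

  if (!length(recs)) {
    return(data.frame(snp_id = character(0), gene_id = character(0),
                      mode = character(0), beta = numeric(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Simulate the expression layer: latent Gaussian plus NB counts
#'
#' Latent expression for gene g, sample s is
#' \code{baseline_g + sum(effects) + ageBeta * age_s + N(0, noiseSd^2)},
#' where an additive effect contributes \code{beta * dosage} and a het_peak
#' effect \code{beta * [dosage == 1]}. Counts, when requested, are drawn
#' negative-binomial with mean \code{libSize_s * exp(latent_gs) / sum_g
#' exp(latent_gs)} and dispersion \code{nbDispersion}, emulating an RNA-seq
#' count matrix over the latent layer. Genes with no truth record are pure
#' noise.
#'
#' @param geno a \linkS4class{GenotypeExperiment}.
#' @param genes GRanges of gene models (defines the gene set and order).
#' @param truth effect ledger from \code{\link{plantEffects}}.
#' @param covariates data.frame with \code{sample_id}, \code{age}.
#' @param ageBeta age effect in latent sd per month (default 0).
#' @param noiseSd residual sd of the latent layer.
#' @param baselineSd sd of per-gene baselines (log-abundance spread).
#' @param nbDispersion negative-binomial dispersion (size = 1/dispersion).
#' @param libSizeRange min/max library size per sample.
#' @param counts logical; also draw the count layer.
#' @param seed optional integer seed.
#' @return list with \code{latent} (genes x samples) and \code{counts}
#'   (integer matrix, or NULL when \code{counts = FALSE}).
#' @export
simulateExpression <- function(geno, genes, truth, covariates, ageBeta = 0,
                               noiseSd = 1, baselineSd = 1.5,
                               nbDispersion = 0.1,
                               libSizeRange = c(8e5, 1.2e6), counts = TRUE,
                               seed = NULL) {
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  if (nbDispersion <= 0) stop("nbDispersion must be > 0")
  if (!is.null(seed)) set.seed(seed)
  d <- dosage(geno)
  samples <- colnames(d)
  if (!setequal(samples, covariates$sample_id)) {
    stop("shape error: covariate samples do not match genotype samples")
  }
  age <- covariates$age[match(samples, covariates$sample_id)]
  gIds <- S4Vectors::mcols(genes)$gene_id
  nG <- length(gIds); nS <- length(samples)
  baseline <- rnorm(nG, 0, baselineSd)
  latent <- matrix(rnorm(nG * nS, 0, noiseSd), nrow = nG) +
    baseline + rep(ageBeta * age, each = nG)
  dimnames(latent) <- list(gIds, samples)
  if (nrow(truth)) {
    vIdx <- match(truth$snp_id, rownames(d))
    gIdx <- match(truth$gene_id, gIds)
    if (anyNA(vIdx) || anyNA(gIdx)) {
      stop("shape error: truth refers to unknown SNP or gene ids")
    }
    for (r in seq_len(nrow(truth))) {
      g <- d[vIdx[r], ]
      g[is.na(g)] <- mean(g, na.rm = TRUE)
      eff <- if (truth$mode[r] == "het_peak") as.numeric(g == 1) else g
      latent[gIdx[r], ] <- latent[gIdx[r], ] + truth$beta[r] * eff
    }
  }
  cnt <- NULL
  if (counts) {
    libSize <- runif(nS, libSizeRange[1], libSizeRange[2])
    share <- exp(latent)
    share <- sweep(share, 2, colSums(share), "/")
    mu <- sweep(share, 2, libSize, "*")
    cnt <- matrix(rnbinom(nG * nS, size = 1 / nbDispersion, mu = mu),
                  nrow = nG, dimnames = dimnames(latent))
  }
  list(latent = latent, counts = cnt)
}

#' Simulate a full synthetic study
#'
#' One call producing every input the pipeline consumes, at the emulated
#' cohort's conditions by default: 75 samples, ages N(14.3, 8.8^2) truncated
#' at 1 month, Hardy-Weinberg genotypes with MAF in [0.05, 0.5], a quarter
#' of genes with a planted cis effect, two trans master-regulator hubs (40
#' and 16 distant targets, the larger shared with a cis signal) plus 30
#' singleton trans effects, and a negative-binomial count layer.
#'
#' @param nSamples cohort size.
#' @param config an \linkS4class{EQTLConfig} (supplies the cis window).
#' @param nChrom,chromLen,nGenes,nSnps genome scaffold parameters.
#' @param mafLow,mafHigh,ldBlock,flipProb,missingRate genotype parameters.
#' @param cisFraction,cisBetaMean,cisBetaSd,hotspotSpec,transSingletons,singletonBetaSd,mode,sharedHub,sharedHubCisBeta
#'   effect-planting parameters (see \code{\link{plantEffects}}).
#' @param ageBeta,noiseSd,baselineSd,nbDispersion,libSizeRange,counts
#'   expression parameters (see \code{\link{simulateExpression}}).
#' @param seed integer seed; stage seeds are derived from it.
#' @return list with \code{genes}, \code{variants}, \code{geno},
#'   \code{covariates}, \code{truth}, \code{latent}, \code{counts}.
#' @export
simulateStudy <- function(nSamples = 75L, config = eqtlConfig(),
                          nChrom = 5L, chromLen = 2e7, nGenes = 300L,
                          nSnps = 1500L, mafLow = 0.05, mafHigh = 0.5,
                          ldBlock = 1L, flipProb = 0.1, missingRate = 0,
                          cisFraction = 0.25, cisBetaMean = 0,
                          cisBetaSd = 1.5,
                          hotspotSpec = list(c(40, 1.5), c(16, 1.5)),
                          transSingletons = 30L, singletonBetaSd = 1.5,
                          mode = "additive", sharedHub = TRUE,
                          sharedHubCisBeta = 3,
                          ageBeta = 0, noiseSd = 1, baselineSd = 1.5,
                          nbDispersion = 0.1, libSizeRange = c(8e5, 1.2e6),
                          counts = TRUE, seed = config@seed) {
  seed <- as.integer(seed)
  genome <- simulateGenome(nChrom, chromLen, nGenes, nSnps, seed = seed)
  ages <- simulateAges(nSamples, seed = seed + 1L)
  geno <- simulateGenotypes(genome$variants, nSamples, mafLow, mafHigh,
                            ldBlock, flipProb, missingRate, seed = seed + 2L)
  truth <- plantEffects(genome$genes, genome$variants,
                        cisWindow = config@cisWindow,
                        cisFraction = cisFraction,
                        cisBetaMean = cisBetaMean, cisBetaSd = cisBetaSd,
                        hotspotSpec = hotspotSpec,
                        transSingletons = transSingletons,
                        singletonBetaSd = singletonBetaSd, mode = mode,
                        sharedHub = sharedHub,
                        sharedHubCisBeta = sharedHubCisBeta,
                        seed = seed + 3L)
  expr <- simulateExpression(geno, genome$genes, truth, ages,
                             ageBeta = ageBeta, noiseSd = noiseSd,
                             baselineSd = baselineSd,
                             nbDispersion = nbDispersion,
                             libSizeRange = libSizeRange, counts = counts,
                             seed = seed + 4L)
  list(genes = genome$genes, variants = genome$variants, geno = geno,
       covariates = ages, truth = truth, latent = expr$latent,
       counts = expr$counts)
}
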