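#' @include AllClasses.R
#' @importFrom utils read.delim write.table
NULL

# Natural chromosome ordering: numeric names numerically, then others
# alphabetically (X, Y, MT ...).
chromOrder <- function(chroms) {
  u <- unique(as.character(chroms))
  num <- suppressWarnings(as.numeric(u))
  u[order(is.na(num), num, u)]
}

#' Construct a GenotypeExperiment
#'
#' @param variants width-1 \code{GRanges} with mcols \code{snp_id},
#'   \code{ref}, \code{alt} (and optionally \code{maf}).
#' @param dosageMatrix variants x samples matrix of ALT-allele counts
#'   (0/1/2, NA for missing); column names are sample ids.
#' @return A \linkS4class{GenotypeExperiment}.
#' @export
GenotypeExperiment <- function(variants, dosageMatrix) {
  stopifnot(is(variants, "GRanges"), is.matrix(dosageMatrix))
  if (length(variants) != nrow(dosageMatrix)) {
    stop("number of variants does not match rows of the dosage matrix")
  }
  rownames(dosageMatrix) <- S4Vectors::mcols(variants)$snp_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosageMatrix),
    rowRanges = variants)
  new("GenotypeExperiment", se)
}

# Convert a matrix of VCF GT strings to ALT-allele dosages. Enforces diploid
# calls; "./." and ".|." become NA.
gtToDosage <- function(gt) {
  u <- unique(as.character(gt))
  alleles <- strsplit(u, "[/|]")
  if (any(lengths(alleles) != 2L)) {
    bad <- u[lengths(alleles) != 2L]
    stop("unsupported ploidy in GT field: ", paste(unique(bad), collapse = ", "))
  }
  tok <- unlist(alleles)
  if (!all(tok %in% c("0", "1", "."))) {
    stop("GT alleles other than 0/1/. found; only biallelic records are supported")
  }
  map <- vapply(alleles, function(a) {
    if (any(a == ".")) NA_real_ else sum(a == "1")
  }, numeric(1))
  names(map) <- u
  out <- matrix(map[as.character(gt)], nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  out
}

#' Read genotypes from a VCF file as allele dosages
#'
#' Parses a VCF v4.x file (via \code{VariantAnnotation::readVcf}) and codes
#' each diploid hard call as the number of ALT alleles (0, 1, 2); missing
#' calls (\code{./.}) become \code{NA} and are excluded from MAF denominators
#' downstream. Positions stay 1-based as in the VCF. Multi-allelic records
#' are rejected by default.
#'
#' @param path path to a VCF file.
#' @param multiAllelic \code{"error"} (default) or \code{"drop"}.
#' @return A \linkS4class{GenotypeExperiment}.
#' @export
readVcfDosage <- function(path, multiAllelic = c("error", "drop")) {
  multiAllelic <- match.arg(multiAllelic)
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path, genome = "unspecified")),
    error = function(e) stop("malformed VCF: ", conditionMessage(e)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  altList <- VariantAnnotation::alt(vcf)
  nAlt <- lengths(altList)
  if (any(nAlt != 1L)) {
    if (multiAllelic == "error") {
      stop(sum(nAlt != 1L), " multi-allelic record(s) found; ",
           "re-run with multiAllelic = \"drop\" or split upstream")
    }
    keep <- nAlt == 1L
    vcf <- vcf[keep, ]
    rr <- rr[keep]
    altList <- altList[keep]
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  dos <- gtToDosage(gt)
  variants <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(rr),
    ranges = IRanges::IRanges(start = GenomicRanges::start(rr), width = 1L))
  S4Vectors::mcols(variants)$snp_id <- paste0(
    as.character(GenomicRanges::seqnames(rr)), ":", GenomicRanges::start(rr))
  S4Vectors::mcols(variants)$ref <- as.character(VariantAnnotation::ref(vcf))
  S4Vectors::mcols(variants)$alt <- as.character(unlist(altList))
  GenotypeExperiment(variants, dos)
}

#' Write a GenotypeExperiment as a minimal VCF
#'
#' Emits VCF v4.2 with CHROM/POS/ID/REF/ALT and a GT-only FORMAT column per
#' sample; dosages 0/1/2 become \code{0/0}, \code{0/1}, \code{1/1} and
#' \code{NA} becomes \code{./.}. Read-back with \code{\link{readVcfDosage}}
#' is a lossless round trip for these fields.
#'
#' @param geno a \linkS4class{GenotypeExperiment}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeVcfDosage <- function(geno, path) {
  vi <- variantInfo(geno)
  d <- dosage(geno)
  gtCodes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtCodes[d[ok] + 1L]
  chroms <- chromOrder(vi$chrom)
  maxPos <- vapply(chroms, function(ch) max(vi$pos[vi$chrom == ch]), numeric(1))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chroms, as.integer(maxPos + 1000)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(d)), collapse = "\t"))
  body <- paste(vi$chrom, vi$pos, vi$snp_id, vi$ref, vi$alt, ".", "PASS", ".",
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read gene models from a BED-like TSV
#'
#' Expects tab-separated columns \code{chrom, start, end, strand, gene_id,
#' symbol} with 1-based inclusive coordinates (declared in a leading
#' \code{#} comment, which is ignored on read). Output is sorted by
#' (chrom, start); duplicated gene ids and malformed rows are rejected.
#'
#' @param path path to the gene-model TSV.
#' @return A \code{GRanges} with mcols \code{gene_id} and \code{symbol}.
#' @export
readGeneModels <- function(path) {
  if (!file.exists(path)) stop("gene-model file not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "strand", "gene_id", "symbol")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("gene-model file lacks columns: ", paste(miss, collapse = ", "))
  if (any(df$start >= df$end)) {
    stop("coordinate error: start >= end for gene(s) ",
         paste(df$gene_id[df$start >= df$end], collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop("unknown strand symbol: ",
         paste(unique(df$strand[!df$strand %in% c("+", "-")]), collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicated gene id(s): ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  df <- df[order(match(df$chrom, chromOrder(df$chrom)), df$start), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = chromOrder(df$chrom)),
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$symbol <- df$symbol
  names(gr) <- df$gene_id
  gr
}

#' Write gene models to a BED-like TSV
#'
#' @param genes a \code{GRanges} with mcols \code{gene_id}, \code{symbol}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(genes)),
    start = GenomicRanges::start(genes),
    end = GenomicRanges::end(genes),
    strand = as.character(GenomicRanges::strand(genes)),
    gene_id = S4Vectors::mcols(genes)$gene_id,
    symbol = S4Vectors::mcols(genes)$symbol,
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# coordinates: 1-based inclusive", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write a genes-x-samples matrix as TSV
#'
#' First column \code{gene_id}, remaining columns one per sample.
#'
#' @param path file path.
#' @return \code{readMatrixTSV}: a numeric matrix with gene-id rownames.
#' @export
readMatrixTSV <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' @rdname readMatrixTSV
#' @param m matrix with rownames (gene ids) and colnames (sample ids).
#' @export
writeMatrixTSV <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write the covariate table
#'
#' Tab-separated columns \code{sample_id} and \code{age} (months); one row
#' per sample, ages must be positive.
#'
#' @param path file path.
#' @return \code{readCovariates}: a data.frame with columns
#'   \code{sample_id}, \code{age}.
#' @export
readCovariates <- function(path) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "age") %in% colnames(df))) {
    stop("covariate file must have columns sample_id and age")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in covariates")
  if (any(df$age <= 0)) stop("ages must be positive")
  df
}

#' @rdname readCovariates
#' @param covariates data.frame with \code{sample_id} and \code{age}.
#' @export
writeCovariates <- function(covariates, path) {
  write.table(covariates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write the planted-effect truth table
#'
#' Columns \code{snp_id, gene_id, mode, beta, class}; the generator's ledger
#' of planted effects, used by recovery tests.
#'
#' @param path file path.
#' @return \code{readEffectTruth}: a data.frame.
#' @export
readEffectTruth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "gene_id", "mode", "beta", "class")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("truth file lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' @rdname readEffectTruth
#' @param truth the truth data.frame.
#' @export
writeEffectTruth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One term per line: \code{term_id<TAB>term_name<TAB>gene1<TAB>gene2...}.
#'
#' @param path path to a GMT file.
#' @return A named list of character vectors (names are term ids) with a
#'   \code{termNames} attribute mapping term id to description.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    stop("malformed GMT line(s): need term_id, term_name and >= 1 gene")
  }
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicated term ids in GMT")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- ids
  attr(sets, "termNames") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2L), ids)
  sets
}

# Shared TSV writer for result tables (fixed column order, no quoting).
writeResultTable <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
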