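#' @include AllClasses.R scan.R
#' @importFrom stats phyper setNames
NULL

#' Hypergeometric over-representation analysis
#'
#' Right-tailed hypergeometric test per term: with background size N, term
#' size K (after intersection with the background), query size n, and
#' overlap k, \code{p = P(X >= k)}. Bonferroni (\code{min(1, p * m)}) and BH
#' over the m tested terms are both reported. Terms empty after background
#' intersection are skipped with a message.
#'
#' @param queryGenes character vector of query gene ids (subset of the
#'   background).
#' @param termSets named list of gene-id vectors (e.g. from
#'   \code{\link{readGmt}}).
#' @param background character vector: the gene universe (typically all
#'   genes surviving the expression filter).
#' @return data.frame with \code{term_id, term_name, k, K, n, N, p, p_bonf,
#'   p_bh}, sorted by p.
#' @export
hypergeomEnrich <- function(queryGenes, termSets, background) {
  queryGenes <- unique(queryGenes)
  background <- unique(background)
  if (!length(queryGenes)) stop("empty query gene set")
  if (!all(queryGenes %in% background)) {
    stop("query genes must be a subset of the background")
  }
  termNames <- attr(termSets, "termNames")
  if (is.null(termNames)) {
    termNames <- setNames(names(termSets), names(termSets))
  }
  sets <- lapply(termSets, intersect, background)
  keep <- lengths(sets) > 0L
  if (any(!keep)) {
    message(sum(!keep), " term(s) empty after background intersection; skipped")
  }
  sets <- sets[keep]
  if (!length(sets)) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), p_bonf = numeric(0),
                      p_bh = numeric(0), stringsAsFactors = FALSE))
  }
  N <- length(background)
  n <- length(queryGenes)
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(queryGenes, s)), integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  m <- length(sets)
  out <- data.frame(
    term_id = names(sets),
    term_name = unname(termNames[names(sets)]),
    k = unname(k), K = unname(K), n = n, N = N, p = unname(p),
    p_bonf = pmin(1, unname(p) * m),
    p_bh = bhFdr(pmin(unname(p), 1), m),
    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohen's kappa between two terms' gene memberships
#'
#' Both terms are turned into binary membership vectors over the background;
#' kappa is \code{(po - pe) / (1 - pe)} with observed agreement po and
#' chance agreement pe from the marginals. Returns \code{NA} (undefined)
#' when pe = 1, i.e. both terms empty or both equal to the background.
#'
#' @param termA,termB character vectors of gene ids.
#' @param background character vector: the gene universe.
#' @return Kappa in [-1, 1], or NA when undefined.
#' @export
termKappa <- function(termA, termB, background) {
  background <- unique(background)
  a <- background %in% termA
  b <- background %in% termB
  po <- mean(a == b)
  pA <- mean(a); pB <- mean(b)
  pe <- pA * pB + (1 - pA) * (1 - pB)
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Pairwise kappa matrix for a term collection
#'
#' @param termSets named list of gene-id vectors.
#' @param background character vector: the gene universe.
#' @return Symmetric matrix of pairwise kappa scores (diagonal 1; NA where
#'   undefined).
#' @export
kappaMatrix <- function(termSets, background) {
  background <- unique(background)
  memb <- vapply(termSets, function(s) background %in% s,
                 logical(length(background)))
  m <- length(termSets)
  km <- matrix(NA_real_, m, m, dimnames = list(names(termSets), names(termSets)))
  for (i in seq_len(m)) {
    for (j in i:m) {
      km[i, j] <- km[j, i] <- termKappa(termSets[[i]], termSets[[j]],
                                        background)
    }
  }
  km
}

#' Cluster terms by kappa-linked connected components
#'
#' Builds a graph with an edge between terms whose kappa is at least
#' \code{kappaMin} and takes connected components. Components with two or
#' more terms are clusters (ids 1, 2, ... by decreasing size, ties by first
#' term); singleton terms are unclustered (\code{NA}), mirroring the
#' convention of dropping isolated nodes from grouped output.
#'
#' @param termSets named list of gene-id vectors.
#' @param background character vector: the gene universe.
#' @param kappaMin linkage threshold (default 0.4).
#' @return Named integer vector of cluster ids (NA for singletons).
#' @export
clusterTerms <- function(termSets, background, kappaMin = 0.4) {
  m <- length(termSets)
  ids <- names(termSets)
  if (m == 0L) return(setNames(integer(0), character(0)))
  km <- kappaMatrix(termSets, background)
  adj <- !is.na(km) & km >= kappaMin
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  membership <- comp$membership
  sizes <- comp$csize[membership]
  out <- rep(NA_integer_, m)
  multi <- sizes >= 2L
  if (any(multi)) {
    comps <- unique(membership[multi])
    # order clusters by decreasing size, then first appearance
    firstPos <- vapply(comps, function(cc) min(which(membership == cc)),
                       integer(1))
    ord <- order(-comp$csize[comps], firstPos)
    relabel <- setNames(seq_along(comps), comps[ord])
    out[multi] <- relabel[as.character(membership[multi])]
  }
  setNames(out, ids)
}

#' Enrichment with kappa clustering
#'
#' Runs \code{\link{hypergeomEnrich}} and attaches kappa-component cluster
#' ids for the tested terms.
#'
#' @inheritParams hypergeomEnrich
#' @param kappaMin kappa linkage threshold.
#' @return The enrichment data.frame with an extra \code{cluster_id} column.
#' @export
enrichTerms <- function(queryGenes, termSets, background, kappaMin = 0.4) {
  enr <- hypergeomEnrich(queryGenes, termSets, background)
  if (!nrow(enr)) {
    enr$cluster_id <- integer(0)
    return(enr)
  }
  tested <- termSets[enr$term_id]
  cl <- clusterTerms(tested, background, kappaMin)
  enr$cluster_id <- unname(cl[enr$term_id])
  enr
}
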