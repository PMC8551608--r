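#' Hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more annotated proteins when drawing `n`
#' proteins without replacement from a universe of `N` proteins of which `K`
#' belong to the pathway: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' Terms are accumulated from log-binomial coefficients so the tail is
#' numerically stable for universes of at least 10^4 proteins.
#'
#' @param k observed overlap (0 <= k <= min(n, K)).
#' @param K number of universe proteins annotated to the pathway.
#' @param n number of submitted proteins found in the universe.
#' @param N universe size.
#' @return upper-tail probability in (0, 1]. All arguments are vectorized.
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
  args <- cbind(k = as.numeric(k), K = as.numeric(K), n = as.numeric(n),
                N = as.numeric(N))
  if (any(is.na(args)))
    stop("domain error: missing value in hypergeometric arguments",
         call. = FALSE)
  if (any(args != floor(args)) || any(args < 0))
    stop("domain error: arguments must be nonnegative integers",
         call. = FALSE)
  bad <- args[, "k"] > pmin(args[, "n"], args[, "K"]) |
    args[, "K"] > args[, "N"] | args[, "n"] > args[, "N"]
  if (any(bad))
    stop("domain error: need k <= min(n, K), K <= N, n <= N", call. = FALSE)
  vapply(seq_len(nrow(args)), function(j) {
    k <- args[j, "k"]; K <- args[j, "K"]; n <- args[j, "n"]; N <- args[j, "N"]
    if (k == 0) return(1)
    i <- k:min(n, K)
    logTerms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    mx <- max(logTerms)
    min(1, exp(mx) * sum(exp(logTerms - mx)))
  }, numeric(1))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_(i) = min_{j >= i} p_(j) * m / j`, clipped at 1, returned in the
#' input order; tied raw p-values receive equal adjusted values. `m`
#' defaults to the number of p-values but can be set larger when only a
#' subset of the tested family is passed in.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @param m family size (default `length(p)`).
#' @return adjusted p-values, same length and order as `p`.
#' @export
bhAdjust <- function(p, m = length(p)) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (m < length(p)) stop("family size m cannot be below length(p)",
                          call. = FALSE)
  o <- order(p, method = "radix")
  ranked <- p[o] * m / seq_along(p)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(length(p))
  out[o] <- adj
  out
}

#' Depth of each pathway in the hierarchy
#'
#' Depth is the shortest directed path length from any root (a node that
#' never occurs as a child). IDs absent from the hierarchy get `NA`.
#'
#' @param hierarchy a \linkS4class{PathwayHierarchy}.
#' @param ids pathway stable IDs to report (default: all hierarchy nodes).
#' @return named numeric vector of depths.
#' @export
pathwayDepths <- function(hierarchy, ids = NULL) {
  stopifnot(is(hierarchy, "PathwayHierarchy"))
  nodes <- pathwayIds(hierarchy)
  if (is.null(ids)) ids <- nodes
  depths <- stats::setNames(rep(NA_real_, length(ids)), ids)
  if (length(nodes) == 0L) return(depths)
  g <- igraph::graph_from_data_frame(hierarchyEdges(hierarchy),
                                     directed = TRUE, vertices = nodes)
  roots <- hierarchyRoots(hierarchy)
  d <- igraph::distances(g, v = roots, to = nodes, mode = "out")
  best <- apply(d, 2, min)
  hit <- ids %in% nodes
  depths[hit] <- best[ids[hit]]
  depths
}

#' Drop high-level pathways from a candidate list
#'
#' Keeps stable IDs whose hierarchy depth is at least `minDepth`; top-level
#' collective terms (depth 0 roots, e.g. broad categories like "Cell Cycle")
#' are excluded at the default `minDepth = 1`. IDs missing from the
#' hierarchy are retained with a warning rather than silently deleted.
#'
#' @param stIds character vector of pathway stable IDs.
#' @param hierarchy a \linkS4class{PathwayHierarchy}.
#' @param minDepth minimum depth to keep (default 1).
#' @return the surviving stable IDs, input order preserved.
#' @export
pruneHighLevel <- function(stIds, hierarchy, minDepth = 1L) {
  stopifnot(minDepth >= 0L)
  if (minDepth == 0L || length(stIds) == 0L) return(stIds)
  depths <- pathwayDepths(hierarchy, stIds)
  unknown <- is.na(depths)
  if (any(unknown))
    warning(sprintf("%d pathway(s) missing from the hierarchy kept: %s",
                    sum(unknown),
                    paste(stIds[unknown], collapse = ", ")), call. = FALSE)
  stIds[unknown | depths >= minDepth]
}

#' Pathway overrepresentation test for one drug profile
#'
#' Tests each candidate pathway for overrepresentation of the submitted
#' protein set by the hypergeometric upper tail, adjusts across the tested
#' pathways (those with overlap >= 1) by Benjamini-Hochberg, and reports
#' pathways passing the FDR cutoff after disease exclusion and hierarchy
#' pruning, sorted by (fdr, p-value, stId).
#'
#' The universe defaults to the union of member accessions over the
#' (non-disease, when excluded) annotations; pass `universe` for an
#' explicit protein list. Submitted accessions outside the universe are
#' counted as not found and excluded from the test.
#'
#' @param accessions character vector of submitted protein accessions, or a
#'   \linkS4class{TargetProfiles} together with `drug`.
#' @param pathways a \linkS4class{PathwaySet}.
#' @param hierarchy a \linkS4class{PathwayHierarchy}, or `NULL` to skip
#'   pruning.
#' @param fdrCutoff report pathways with FDR at or below this value
#'   (default 0.05).
#' @param minDepth minimum hierarchy depth (default 1); ignored when
#'   `hierarchy` is `NULL`.
#' @param excludeDisease drop disease-flagged pathways from both the
#'   universe and the candidates (default `TRUE`).
#' @param universe optional explicit universe accession vector.
#' @param drug drug identifier: required when `accessions` is a
#'   TargetProfiles, otherwise used as a label.
#' @return an \linkS4class{EnrichResult}.
#' @export
runOra <- function(accessions, pathways, hierarchy = NULL,
                   fdrCutoff = 0.05, minDepth = 1L, excludeDisease = TRUE,
                   universe = NULL, drug = "query") {
  stopifnot(is(pathways, "PathwaySet"), fdrCutoff > 0, fdrCutoff <= 1)
  if (is(accessions, "TargetProfiles"))
    accessions <- profileAccessions(accessions, drug)
  accessions <- unique(accessions)

  keepPw <- if (excludeDisease) !pathways@isDisease else
    rep(TRUE, length(pathways@stId))
  members <- pathways@members[keepPw]
  stIds <- pathways@stId[keepPw]
  names <- pathways@name[keepPw]

  if (is.null(universe)) {
    universe <- sort(unique(unlist(members)))
  } else {
    universe <- sort(unique(universe))
  }
  N <- length(universe)
  found <- intersect(accessions, universe)
  n <- length(found)

  emptyTab <- data.frame(stId = character(), name = character(),
                         k = integer(), K = integer(), n = integer(),
                         N = integer(), pValue = numeric(), fdr = numeric(),
                         stringsAsFactors = FALSE)
  if (n == 0L)
    return(new("EnrichResult", drugId = drug, table = emptyTab,
               status = "no-proteins-found",
               nSubmitted = length(accessions), nFound = 0L,
               universeSize = N, nTested = 0L))

  Kv <- vapply(members, function(mm) length(intersect(mm, universe)),
               integer(1))
  kv <- vapply(members, function(mm) length(intersect(mm, found)),
               integer(1))
  tested <- kv >= 1L
  mTested <- sum(tested)
  tab <- emptyTab
  if (mTested > 0L) {
    p <- hypergeomUpperTail(kv[tested], Kv[tested], n, N)
    fdr <- bhAdjust(p)
    tab <- data.frame(stId = stIds[tested], name = names[tested],
                      k = kv[tested], K = Kv[tested], n = n, N = N,
                      pValue = p, fdr = fdr, stringsAsFactors = FALSE)
    tab <- tab[tab$fdr <= fdrCutoff, , drop = FALSE]
    if (!is.null(hierarchy) && nrow(tab) > 0L) {
      keepIds <- pruneHighLevel(tab$stId, hierarchy, minDepth)
      tab <- tab[tab$stId %in% keepIds, , drop = FALSE]
    }
    o <- order(tab$fdr, tab$pValue, tab$stId, method = "radix")
    tab <- tab[o, , drop = FALSE]
    rownames(tab) <- NULL
  }
  new("EnrichResult", drugId = drug, table = tab, status = "ok",
      nSubmitted = length(accessions), nFound = n,
      universeSize = N, nTested = as.integer(mTested))
}
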