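#' Define a drug group for pathway-profile comparison
#'
#' @param label group label, e.g. `"cardiotoxic"`.
#' @param results named list mapping drug_id to its character vector of
#'   significant pathway stable IDs (may be empty for a drug), or a list of
#'   \linkS4class{EnrichResult} objects.
#' @return a `DrugGroup` (plain list with class attribute).
#' @export
drugGroup <- function(label, results) {
  stopifnot(is.character(label), length(label) == 1L)
  if (length(results) > 0L && is(results[[1]], "EnrichResult")) {
    nm <- vapply(results, function(r) r@drugId, character(1))
    results <- lapply(results, function(r) resultTable(r)$stId)
    names(results) <- nm
  }
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("results must be named by drug_id", call. = FALSE)
  results <- lapply(results, function(x) sort(unique(as.character(x))))
  structure(list(label = label, results = results), class = "DrugGroup")
}

#' Affected-compound frequency per pathway within a group
#'
#' For each pathway hit by at least one drug, the fraction of the group's
#' drugs whose significant set contains it. The denominator is the number
#' of drugs with at least one significant pathway; drugs with empty sets
#' are recorded in the output metadata but excluded from the denominator.
#'
#' @param group a `DrugGroup` from [drugGroup()].
#' @return data.frame with columns `st_id`, `label`, `n_hit`, `n_group`,
#'   `fraction`, ordered by fraction descending then `st_id`; attribute
#'   `n_empty_drugs` counts the excluded drugs.
#' @export
pathwayFrequencies <- function(group) {
  stopifnot(inherits(group, "DrugGroup"))
  nonEmpty <- group$results[lengths(group$results) > 0L]
  nEmpty <- length(group$results) - length(nonEmpty)
  if (length(nonEmpty) == 0L)
    stop("no drugs with significant pathways in group ", group$label,
         call. = FALSE)
  hits <- table(unlist(nonEmpty, use.names = FALSE))
  out <- data.frame(st_id = names(hits), label = group$label,
                    n_hit = as.integer(hits),
                    n_group = length(nonEmpty),
                    fraction = as.integer(hits) / length(nonEmpty),
                    stringsAsFactors = FALSE)
  o <- order(-out$fraction, out$st_id, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_empty_drugs") <- nEmpty
  out
}

#' Frequency-threshold pathway sets, intersections and exclusives
#'
#' Per group, the pathways affected by at least `minFraction` of its drugs
#' (inclusive threshold); plus every pairwise intersection and, per group,
#' the pathways exclusive to it among the thresholded sets.
#'
#' @param groups list of `DrugGroup` objects.
#' @param minFraction threshold in (0, 1], e.g. 0.1 for "at least 10%".
#' @return list with `sets` (named list per label), `intersections`
#'   (named list per unordered label pair, `"A|B"`), `exclusive`
#'   (named list per label).
#' @export
thresholdSets <- function(groups, minFraction) {
  stopifnot(minFraction > 0, minFraction <= 1)
  labels <- vapply(groups, function(g) g$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate group labels", call. = FALSE)
  sets <- lapply(groups, function(g) {
    fr <- pathwayFrequencies(g)
    sort(fr$st_id[fr$fraction >= minFraction])
  })
  names(sets) <- labels
  inter <- list()
  if (length(sets) > 1L) {
    cmb <- utils::combn(labels, 2L, simplify = FALSE)
    for (pair in cmb)
      inter[[paste(pair, collapse = "|")]] <-
        sort(intersect(sets[[pair[1]]], sets[[pair[2]]]))
  }
  excl <- lapply(labels, function(lb)
    sort(setdiff(sets[[lb]], unlist(sets[setdiff(labels, lb)],
                                    use.names = FALSE))))
  names(excl) <- labels
  list(sets = sets, intersections = inter, exclusive = excl)
}

#' Drug-pathway bipartite edge list across groups
#'
#' One edge per (drug, significant pathway) within each group; a pair
#' occurring in several groups appears once per group. Deterministically
#' ordered, loadable by standard network tools.
#'
#' @param groups list of `DrugGroup` objects.
#' @return data.frame with columns `drug_id`, `st_id`, `group`.
#' @export
bipartiteEdges <- function(groups) {
  parts <- lapply(groups, function(g) {
    if (sum(lengths(g$results)) == 0L)
      return(data.frame(drug_id = character(), st_id = character(),
                        group = character(), stringsAsFactors = FALSE))
    data.frame(
      drug_id = rep(names(g$results), lengths(g$results)),
      st_id = unlist(g$results, use.names = FALSE),
      group = g$label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- unique(out)
  o <- order(out$group, out$drug_id, out$st_id, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score discovered drug-pathway links against a reference edge list
#'
#' Splits each drug's discovered pathway set against a reference
#' compound-pathway edge list (same drug-ID namespace; translate upstream
#' via the crossref machinery): recovered = discovered and referenced,
#' novel = discovered only, missed = referenced only.
#'
#' @param discovered named list mapping drug_id to discovered stable IDs.
#' @param reference data.frame with columns `drug_id`, `st_id`.
#' @return list with `per_drug` data.frame (`drug_id`, `recovered`,
#'   `novel`, `missed`) and `overall` totals.
#' @export
noveltyVsReference <- function(discovered, reference) {
  .requireColumns(reference, c("drug_id", "st_id"), "reference edge list")
  refSets <- split(reference$st_id, reference$drug_id)
  drugsAll <- sort(names(discovered))
  rows <- lapply(drugsAll, function(d) {
    disc <- unique(discovered[[d]])
    ref <- unique(refSets[[d]])
    data.frame(drug_id = d,
               recovered = length(intersect(disc, ref)),
               novel = length(setdiff(disc, ref)),
               missed = length(setdiff(ref, disc)),
               stringsAsFactors = FALSE)
  })
  perDrug <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  overall <- list(recovered = sum(perDrug$recovered),
                  novel = sum(perDrug$novel),
                  missed = sum(perDrug$missed),
                  n_drugs = nrow(perDrug))
  list(per_drug = perDrug, overall = overall)
}
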