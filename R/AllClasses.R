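#' @import methods
NULL

## UniProt accession syntax (both historical forms), anchored.
.UNIPROT_RE <- paste0(
  "^([OPQ][0-9][A-Z0-9]{3}[0-9]",
  "|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})$"
)

#' Does a string look like a UniProt accession?
#'
#' @param x character vector.
#' @return logical vector, `TRUE` where `x` matches the UniProt accession
#'   syntax (e.g. `"P21964"`).
#' @export
isUniprotAccession <- function(x) grepl(.UNIPROT_RE, x)

.SOURCES <- c("chembl", "drugbank", "ttd", "pharmgkb", "iuphar")

#' TargetProfiles: deduplicated drug to protein-pool mapping
#'
#' One row per unique (drug, accession) pair, pooled across the source
#' databases; the `sources` column keeps per-source provenance as a
#' semicolon-joined, sorted list. The `metadata` slot carries run statistics
#' (e.g. tissue-filter drop counts).
#'
#' @slot pairs data.frame with columns `drug_id`, `accession`, `sources`.
#' @slot metadata list of free-form run statistics.
#' @export
setClass("TargetProfiles",
  representation(pairs = "data.frame", metadata = "list"),
  prototype(
    pairs = data.frame(drug_id = character(), accession = character(),
                       sources = character(), stringsAsFactors = FALSE),
    metadata = list()
  )
)

setValidity("TargetProfiles", function(object) {
  p <- object@pairs
  need <- c("drug_id", "accession", "sources")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(p[c("drug_id", "accession")]))
    return("duplicate (drug_id, accession) pairs")
  if (nrow(p) > 0L) {
    if (any(!nzchar(p$sources)))
      return("every accession needs a nonempty source set")
    if (!all(isUniprotAccession(p$accession)))
      return("accession not matching UniProt syntax")
  }
  TRUE
})

#' PathwaySet: pathway annotation collection
#'
#' Pathway stable IDs with display names, member accession sets, a disease
#' flag and the species taxon (9606 for human).
#'
#' @slot stId character vector of unique stable IDs (e.g. "R-HSA-1296071").
#' @slot name display names, parallel to `stId`.
#' @slot members named list of character vectors (member accessions).
#' @slot isDisease logical, parallel to `stId`.
#' @slot taxId integer species taxon identifiers, parallel to `stId`.
#' @export
setClass("PathwaySet",
  representation(stId = "character", name = "character", members = "list",
                 isDisease = "logical", taxId = "integer"),
  prototype(stId = character(), name = character(), members = list(),
            isDisease = logical(), taxId = integer())
)

setValidity("PathwaySet", function(object) {
  n <- length(object@stId)
  if (length(object@name) != n || length(object@members) != n ||
      length(object@isDisease) != n || length(object@taxId) != n)
    return("all slots must have equal length")
  if (anyDuplicated(object@stId)) return("duplicate pathway stable IDs")
  if (n > 0L && any(lengths(object@members) == 0L))
    return("every pathway needs a nonempty member set")
  TRUE
})

#' PathwayHierarchy: parent to child pathway relations
#'
#' A directed acyclic graph over pathway stable IDs; roots are the IDs that
#' never occur as a child.
#'
#' @slot parent character vector of parent stable IDs.
#' @slot child character vector of child stable IDs, parallel to `parent`.
#' @export
setClass("PathwayHierarchy",
  representation(parent = "character", child = "character"),
  prototype(parent = character(), child = character())
)

setValidity("PathwayHierarchy", function(object) {
  if (length(object@parent) != length(object@child))
    return("parent and child must have equal length")
  if (length(object@parent) > 0L) {
    if (anyDuplicated(paste(object@parent, object@child)))
      return("duplicate parent-child edges")
    g <- igraph::graph_from_data_frame(
      data.frame(from = object@parent, to = object@child), directed = TRUE)
    if (!igraph::is_dag(g)) return("hierarchy contains a cycle")
  }
  TRUE
})

#' EnrichResult: per-drug pathway overrepresentation results
#'
#' Rows are the pathways significant at the FDR cutoff after disease
#' exclusion and hierarchy pruning, sorted by (fdr, p, stId). Counts follow
#' the hypergeometric sampling frame: `k` = overlap, `K` = pathway size in
#' the universe, `n` = submitted proteins found in the universe, `N` =
#' universe size.
#'
#' @slot drugId drug identifier the result belongs to.
#' @slot table data.frame with columns `stId`, `name`, `k`, `K`, `n`, `N`,
#'   `pValue`, `fdr`.
#' @slot status "ok" or "no-proteins-found".
#' @slot nSubmitted number of accessions submitted.
#' @slot nFound number found in the annotation universe.
#' @slot universeSize size of the annotation universe.
#' @slot nTested number of pathways entering the FDR correction (overlap >= 1).
#' @export
setClass("EnrichResult",
  representation(drugId = "character", table = "data.frame",
                 status = "character", nSubmitted = "integer",
                 nFound = "integer", universeSize = "integer",
                 nTested = "integer"),
  prototype(drugId = NA_character_,
            table = data.frame(stId = character(), name = character(),
                               k = integer(), K = integer(), n = integer(),
                               N = integer(), pValue = numeric(),
                               fdr = numeric(), stringsAsFactors = FALSE),
            status = "ok", nSubmitted = 0L, nFound = 0L,
            universeSize = 0L, nTested = 0L)
)

setValidity("EnrichResult", function(object) {
  tb <- object@table
  need <- c("stId", "name", "k", "K", "n", "N", "pValue", "fdr")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (nrow(tb) > 0L) {
    if (any(tb$k < 1L)) return("reported pathways must have overlap k >= 1")
    if (any(tb$k > pmin(tb$n, tb$K))) return("k must be <= min(n, K)")
    if (any(tb$pValue <= 0 | tb$pValue > 1)) return("pValue out of (0, 1]")
    if (any(tb$fdr + 1e-12 < tb$pValue))
      return("BH can only raise p-values: fdr >= pValue must hold")
  }
  if (!object@status %in% c("ok", "no-proteins-found"))
    return("status must be 'ok' or 'no-proteins-found'")
  TRUE
})
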