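#' @rdname TargetProfiles-class
#' @param object,x a \linkS4class{TargetProfiles}.
#' @export
setGeneric("drugIds", function(object) standardGeneric("drugIds"))

#' @rdname TargetProfiles-class
#' @param drug single drug identifier.
#' @export
setGeneric("profileAccessions",
           function(object, drug) standardGeneric("profileAccessions"))

#' @rdname TargetProfiles-class
#' @export
setGeneric("profileTable", function(object) standardGeneric("profileTable"))

#' @rdname PathwaySet-class
#' @param object a \linkS4class{PathwaySet} or
#'   \linkS4class{PathwayHierarchy}.
#' @export
setGeneric("pathwayIds", function(object) standardGeneric("pathwayIds"))

#' @rdname PathwaySet-class
#' @export
setGeneric("pathwayNames", function(object) standardGeneric("pathwayNames"))

#' @rdname PathwaySet-class
#' @export
setGeneric("pathwayMembers",
           function(object) standardGeneric("pathwayMembers"))

#' @rdname PathwaySet-class
#' @export
setGeneric("isDisease", function(object) standardGeneric("isDisease"))

#' @rdname PathwayHierarchy-class
#' @export
setGeneric("hierarchyEdges",
           function(object) standardGeneric("hierarchyEdges"))

#' @rdname PathwayHierarchy-class
#' @export
setGeneric("hierarchyRoots",
           function(object) standardGeneric("hierarchyRoots"))

#' @rdname EnrichResult-class
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' @rdname EnrichResult-class
#' @export
setGeneric("enrichStatus", function(object) standardGeneric("enrichStatus"))

## ---- TargetProfiles methods ----

#' @rdname TargetProfiles-class
#' @export
setMethod("drugIds", "TargetProfiles", function(object)
  sort(unique(object@pairs$drug_id)))

#' @rdname TargetProfiles-class
#' @export
setMethod("profileAccessions", "TargetProfiles", function(object, drug) {
  stopifnot(length(drug) == 1L)
  sort(object@pairs$accession[object@pairs$drug_id == drug])
})

#' @rdname TargetProfiles-class
#' @export
setMethod("profileTable", "TargetProfiles", function(object) object@pairs)

#' @rdname TargetProfiles-class
#' @export
setMethod("length", "TargetProfiles", function(x) length(drugIds(x)))

setMethod("show", "TargetProfiles", function(object) {
  cat("TargetProfiles:", length(drugIds(object)), "drug(s),",
      nrow(object@pairs), "unique drug-protein pair(s)\n")
  if (nrow(object@pairs) > 0L) {
    sizes <- table(object@pairs$drug_id)
    cat("  pool sizes:", paste0(names(sizes), "=", as.integer(sizes),
                                collapse = " "), "\n")
  }
})

## ---- PathwaySet methods ----

#' @rdname PathwaySet-class
#' @export
setMethod("pathwayIds", "PathwaySet", function(object) object@stId)

#' @rdname PathwaySet-class
#' @export
setMethod("pathwayNames", "PathwaySet", function(object)
  stats::setNames(object@name, object@stId))

#' @rdname PathwaySet-class
#' @export
setMethod("pathwayMembers", "PathwaySet", function(object)
  stats::setNames(object@members, object@stId))

#' @rdname PathwaySet-class
#' @export
setMethod("isDisease", "PathwaySet", function(object)
  stats::setNames(object@isDisease, object@stId))

#' @rdname PathwaySet-class
#' @param x a \linkS4class{PathwaySet}.
#' @export
setMethod("length", "PathwaySet", function(x) length(x@stId))

setMethod("show", "PathwaySet", function(object) {
  cat("PathwaySet:", length(object@stId), "pathway(s),",
      sum(object@isDisease), "disease-flagged,",
      length(unique(unlist(object@members))), "distinct member accessions\n")
})

## ---- PathwayHierarchy methods ----

#' @rdname PathwayHierarchy-class
#' @export
setMethod("hierarchyEdges", "PathwayHierarchy", function(object)
  data.frame(parent = object@parent, child = object@child,
             stringsAsFactors = FALSE))

#' @rdname PathwayHierarchy-class
#' @export
setMethod("hierarchyRoots", "PathwayHierarchy", function(object) {
  nodes <- unique(c(object@parent, object@child))
  sort(setdiff(nodes, unique(object@child)))
})

#' @rdname PathwayHierarchy-class
#' @export
setMethod("pathwayIds", "PathwayHierarchy", function(object)
  sort(unique(c(object@parent, object@child))))

setMethod("show", "PathwayHierarchy", function(object) {
  cat("PathwayHierarchy:", length(object@parent), "edge(s),",
      length(pathwayIds(object)), "node(s),",
      length(hierarchyRoots(object)), "root(s)\n")
})

## ---- EnrichResult methods ----

#' @rdname EnrichResult-class
#' @export
setMethod("resultTable", "EnrichResult", function(object) object@table)

#' @rdname EnrichResult-class
#' @export
setMethod("enrichStatus", "EnrichResult", function(object) object@status)

#' @rdname EnrichResult-class
#' @export
setMethod("drugIds", "EnrichResult", function(object) object@drugId)

setMethod("show", "EnrichResult", function(object) {
  cat("EnrichResult for", object@drugId, "-", object@status, "\n")
  cat("  submitted:", object@nSubmitted, " found:", object@nFound,
      " universe:", object@universeSize, " tested:", object@nTested, "\n")
  cat("  significant pathways:", nrow(object@table), "\n")
  if (nrow(object@table) > 0L)
    print(utils::head(object@table[c("stId", "name", "k", "K", "pValue",
                                     "fdr")], 5L), row.names = FALSE)
})
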