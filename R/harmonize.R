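#' Collate per-source target records into deduplicated drug profiles
#'
#' Unions the records of all source adapters per drug, removes duplicate
#' (drug, accession) pairs, and keeps per-source provenance: each retained
#' pair lists the sorted, semicolon-joined set of databases that evidenced
#' it. Drugs contributing zero records are absent from the result.
#'
#' @param records data.frame of target records as produced by the source
#'   adapters (columns `drug_id`, `accession`, `source`, `reviewed`,
#'   `human`, `provenance`), or a list of such data.frames / adapter return
#'   values which are row-bound first.
#' @return a \linkS4class{TargetProfiles} object.
#' @export
buildProfiles <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    parts <- lapply(records, function(x) {
      if (is.data.frame(x)) x else x$records
    })
    records <- do.call(rbind, parts)
  }
  if (is.null(records) || nrow(records) == 0L)
    return(new("TargetProfiles"))
  .requireColumns(records,
                  c("drug_id", "accession", "source", "reviewed", "human"),
                  "target records")
  if (!all(records$reviewed) || !all(records$human))
    stop("adapter bug: record failing the reviewed-human invariant",
         call. = FALSE)
  key <- paste(records$drug_id, records$accession, sep = "\r")
  src <- vapply(split(records$source, key), function(s)
    paste(sort(unique(s)), collapse = ";"), character(1))
  uniq <- records[!duplicated(key), c("drug_id", "accession")]
  uniq$sources <- unname(src[paste(uniq$drug_id, uniq$accession,
                                   sep = "\r")])
  o <- order(uniq$drug_id, uniq$accession, method = "radix")
  uniq <- uniq[o, , drop = FALSE]
  rownames(uniq) <- NULL
  new("TargetProfiles", pairs = uniq)
}

#' Write harmonized profiles as TSV
#'
#' Columns: `drug_id`, `accession`, `sources` (semicolon-joined).
#'
#' @param profiles a \linkS4class{TargetProfiles}.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  stopifnot(is(profiles, "TargetProfiles"))
  .writeTsv(profileTable(profiles), path)
  invisible(path)
}
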