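#' Read a GMT pathway annotation file with a flags sidecar
#'
#' GMT lines are `stId <tab> name <tab> member accessions...`. The sidecar
#' TSV carries per-pathway flags: columns `st_id`, `is_disease`
#' (`true`/`false`), `species_tax_id`.
#'
#' @param gmtPath GMT file path.
#' @param flagsPath flags TSV path; when `NULL`, all pathways are
#'   non-disease human (taxon 9606).
#' @return a \linkS4class{PathwaySet}.
#' @export
readPathwaySet <- function(gmtPath, flagsPath = NULL) {
  lines <- readLines(gmtPath, encoding = "UTF-8")
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short))
    stop("schema error in GMT: every line needs id, name and >= 1 member",
         call. = FALSE)
  stId <- vapply(parts, `[[`, character(1), 1L)
  name <- vapply(parts, `[[`, character(1), 2L)
  members <- lapply(parts, function(x) sort(unique(x[-(1:2)])))
  isDis <- rep(FALSE, length(stId))
  tax <- rep(9606L, length(stId))
  if (!is.null(flagsPath)) {
    fl <- if (is.data.frame(flagsPath)) flagsPath else .readTsv(flagsPath)
    .requireColumns(fl, c("st_id", "is_disease", "species_tax_id"),
                    "pathway flags")
    idx <- match(stId, fl$st_id)
    hit <- !is.na(idx)
    isDis[hit] <- tolower(fl$is_disease[idx[hit]]) %in% c("true", "1", "yes")
    tax[hit] <- as.integer(fl$species_tax_id[idx[hit]])
  }
  new("PathwaySet", stId = stId, name = name,
      members = stats::setNames(members, stId), isDisease = isDis,
      taxId = tax)
}

#' Write a PathwaySet as GMT plus flags sidecar
#'
#' @param pathways a \linkS4class{PathwaySet}.
#' @param gmtPath,flagsPath output paths.
#' @return `gmtPath`, invisibly.
#' @export
writePathwaySet <- function(pathways, gmtPath, flagsPath = NULL) {
  stopifnot(is(pathways, "PathwaySet"))
  lines <- vapply(seq_along(pathways@stId), function(i)
    paste(c(pathways@stId[i], pathways@name[i],
            sort(pathways@members[[i]])), collapse = "\t"), character(1))
  writeLines(lines, gmtPath, useBytes = TRUE)
  if (!is.null(flagsPath))
    .writeTsv(data.frame(st_id = pathways@stId,
                         is_disease = ifelse(pathways@isDisease,
                                             "true", "false"),
                         species_tax_id = pathways@taxId,
                         stringsAsFactors = FALSE), flagsPath)
  invisible(gmtPath)
}

#' Read a parent-child pathway hierarchy TSV
#'
#' Two-column, headerless or headered `parent <tab> child` relations, the
#' layout used for pathway-hierarchy dumps.
#'
#' @param path TSV path or two-column data.frame.
#' @return a \linkS4class{PathwayHierarchy}.
#' @export
readHierarchy <- function(path) {
  if (is.data.frame(path)) {
    df <- path
    names(df)[1:2] <- c("parent", "child")
  } else {
    first <- readLines(path, n = 1L)
    hasHeader <- grepl("parent", first, ignore.case = TRUE)
    df <- utils::read.delim(path, header = hasHeader,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    names(df)[1:2] <- c("parent", "child")
  }
  new("PathwayHierarchy", parent = df$parent, child = df$child)
}

#' Write a hierarchy as parent-child TSV
#'
#' @param hierarchy a \linkS4class{PathwayHierarchy}.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeHierarchy <- function(hierarchy, path) {
  stopifnot(is(hierarchy, "PathwayHierarchy"))
  .writeTsv(hierarchyEdges(hierarchy), path)
  invisible(path)
}

#' Write per-drug enrichment results as a flat CSV
#'
#' Header is exactly `molecule_chembl_id,Names,stIds,fdrs,pValues`; one row
#' per significant (drug, pathway) pair, drugs in the order given, each
#' drug's pathways in the result's (fdr, p, stId) order. Numbers are
#' rendered with up to 10 significant digits so repeated runs are
#' byte-identical.
#'
#' @param results an \linkS4class{EnrichResult} or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeResultsCsv <- function(results, path) {
  if (is(results, "EnrichResult")) results <- list(results)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("molecule_chembl_id,Names,stIds,fdrs,pValues", con,
             useBytes = TRUE)
  for (res in results) {
    tb <- resultTable(res)
    if (nrow(tb) == 0L) next
    lines <- paste(res@drugId, tb$name, tb$stId, .fmtNum(tb$fdr),
                   .fmtNum(tb$pValue), sep = ",")
    writeLines(lines, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Write full enrichment detail as JSON
#'
#' Per drug: status, submitted/found/universe/tested counts and the full
#' result table including the hypergeometric frame (k, K, n, N).
#'
#' @param results an \linkS4class{EnrichResult} or list of them.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeResultsJson <- function(results, path) {
  if (is(results, "EnrichResult")) results <- list(results)
  payload <- lapply(results, function(res) list(
    drug_id = res@drugId,
    status = res@status,
    n_submitted = res@nSubmitted,
    n_found = res@nFound,
    universe_size = res@universeSize,
    n_tested = res@nTested,
    pathways = resultTable(res)
  ))
  names(payload) <- vapply(results, function(r) r@drugId, character(1))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
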