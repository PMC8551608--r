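.SNAPSHOT_FILES <- c("chembl.tsv", "drugbank.tsv", "ttd.tsv",
                     "pharmgkb.tsv", "iuphar.tsv", "crossref.tsv",
                     "expression.tsv", "pathways.gmt", "pathway_flags.tsv",
                     "hierarchy.tsv")

#' Read a snapshot directory into memory
#'
#' Validates that every required file is present before reading anything,
#' then loads the five source snapshots, the crossref, the expression
#' table, the pathway set (GMT + flags) and the hierarchy.
#'
#' @param dir snapshot directory (layout written by [writeUniverse()]).
#' @return list with `snapshots`, `crossref`, `expression`, `pathways`,
#'   `hierarchy`.
#' @export
readSnapshots <- function(dir) {
  missing <- .SNAPSHOT_FILES[!file.exists(file.path(dir, .SNAPSHOT_FILES))]
  if (length(missing) > 0L)
    stop("missing snapshot file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  list(
    snapshots = list(
      chembl = .readTsv(file.path(dir, "chembl.tsv")),
      drugbank = .readTsv(file.path(dir, "drugbank.tsv")),
      ttd = .readTsv(file.path(dir, "ttd.tsv")),
      pharmgkb = .readTsv(file.path(dir, "pharmgkb.tsv")),
      iuphar = .readTsv(file.path(dir, "iuphar.tsv"))),
    crossref = readCrossRef(file.path(dir, "crossref.tsv")),
    expression = readExpression(file.path(dir, "expression.tsv")),
    pathways = readPathwaySet(file.path(dir, "pathways.gmt"),
                              file.path(dir, "pathway_flags.tsv")),
    hierarchy = readHierarchy(file.path(dir, "hierarchy.tsv")))
}

#' Run the full drug-to-pathway pipeline
#'
#' For each drug: collect target records from the five source snapshots,
#' harmonize them into a deduplicated protein pool, optionally restrict to
#' a tissue, and run the pathway overrepresentation test. Drugs absent from
#' every source yield a "no targets found" report row, never an error.
#'
#' @param drugs character vector of ChEMBL-style drug IDs, or a file with
#'   one ID per line.
#' @param snapshots a snapshot directory path, a list from
#'   [readSnapshots()], or a `SyntheticUniverse`.
#' @param tissue optional tissue name; `NULL` skips the tissue filter.
#' @param minNtpm inclusive expression threshold (default 1.0).
#' @param keepUnmeasured keep accessions without expression evidence.
#' @param fdrCutoff,minDepth,excludeDisease enrichment settings, see
#'   [runOra()].
#' @param pchemblMin,includeOrthologLift ChEMBL adapter settings, see
#'   [parseChemblActivities()].
#' @param outDir optional output directory: writes `results.csv` (flat
#'   Table-style CSV), `results.json`, `profiles.tsv`, `report.tsv` and
#'   `rejects.tsv`.
#' @return list with `results` (named list of \linkS4class{EnrichResult}),
#'   `profiles` (post-filter \linkS4class{TargetProfiles}), `report`
#'   (per-drug count data.frame), `rejects` (combined rejects report).
#' @export
runPipeline <- function(drugs, snapshots, tissue = NULL, minNtpm = 1.0,
                        keepUnmeasured = FALSE, fdrCutoff = 0.05,
                        minDepth = 1L, excludeDisease = TRUE,
                        pchemblMin = 5.0, includeOrthologLift = TRUE,
                        outDir = NULL) {
  if (length(drugs) == 1L && file.exists(drugs) &&
      !grepl("^CHEMBL", drugs)) {
    drugs <- readLines(drugs)
    drugs <- trimws(drugs[nzchar(trimws(drugs))])
  }
  malformed <- !grepl("^CHEMBL[0-9]+$", drugs)
  if (any(malformed)) {
    warning("rejecting malformed drug ID(s): ",
            paste(drugs[malformed], collapse = ", "), call. = FALSE)
    drugs <- drugs[!malformed]
  }
  if (length(drugs) == 0L) stop("no valid drug IDs supplied", call. = FALSE)
  if (is.character(snapshots)) snapshots <- readSnapshots(snapshots)

  xref <- readCrossRef(snapshots$crossref)
  adapters <- list(
    chembl = parseChemblActivities(snapshots$snapshots$chembl, xref,
                                   drugs = drugs, pchemblMin = pchemblMin,
                                   includeOrthologLift = includeOrthologLift),
    drugbank = parseDrugbankTargets(snapshots$snapshots$drugbank, xref,
                                    drugs = drugs),
    ttd = parseTtdTargets(snapshots$snapshots$ttd, xref, drugs = drugs),
    pharmgkb = parsePharmgkbTargets(snapshots$snapshots$pharmgkb, xref,
                                    drugs = drugs),
    iuphar = parseIupharTargets(snapshots$snapshots$iuphar, xref,
                                drugs = drugs))
  records <- do.call(rbind, lapply(adapters, `[[`, "records"))
  rejects <- do.call(rbind, lapply(adapters, `[[`, "rejects"))
  rownames(records) <- rownames(rejects) <- NULL

  profiles <- buildProfiles(records)
  rawCounts <- table(factor(records$drug_id, levels = drugs))
  dedupCounts <- table(factor(profileTable(profiles)$drug_id,
                              levels = drugs))
  if (!is.null(tissue))
    profiles <- filterProfiles(profiles, snapshots$expression, xref,
                               tissue = tissue, minNtpm = minNtpm,
                               keepUnmeasured = keepUnmeasured)
  filtCounts <- table(factor(profileTable(profiles)$drug_id,
                             levels = drugs))

  pathways <- snapshots$pathways
  hierarchy <- snapshots$hierarchy
  results <- list()
  report <- list()
  for (d in drugs) {
    accs <- profileAccessions(profiles, d)
    if (length(accs) == 0L) {
      res <- new("EnrichResult", drugId = d, status = "no-proteins-found")
      status <- if (rawCounts[[d]] == 0L) "no targets found"
        else "no proteins found in universe"
    } else {
      res <- suppressWarnings(
        runOra(accs, pathways, hierarchy, fdrCutoff = fdrCutoff,
               minDepth = minDepth, excludeDisease = excludeDisease,
               drug = d))
      status <- if (enrichStatus(res) == "no-proteins-found")
        "no proteins found in universe" else "ok"
    }
    results[[d]] <- res
    report[[d]] <- data.frame(
      drug_id = d, raw_targets = as.integer(rawCounts[[d]]),
      after_dedup = as.integer(dedupCounts[[d]]),
      after_tissue_filter = as.integer(filtCounts[[d]]),
      found_in_universe = res@nFound,
      significant_pathways = nrow(resultTable(res)),
      status = status, stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, c(report, list(make.row.names = FALSE)))

  out <- list(results = results, profiles = profiles, report = report,
              rejects = rejects)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeResultsCsv(results, file.path(outDir, "results.csv"))
    writeResultsJson(results, file.path(outDir, "results.json"))
    writeProfiles(profiles, file.path(outDir, "profiles.tsv"))
    .writeTsv(report, file.path(outDir, "report.tsv"))
    .writeTsv(rejects, file.path(outDir, "rejects.tsv"))
  }
  out
}

#' Compare pathway profiles across drug groups
#'
#' Wraps the group-comparison operations: per-group affected-compound
#' frequencies, threshold sets with intersections and exclusives at each
#' requested fraction, and the bipartite drug-pathway edge list.
#'
#' @param groupTable data.frame (or TSV path) with columns `drug_id`,
#'   `group_label`.
#' @param results named list mapping drug_id to an
#'   \linkS4class{EnrichResult} or to a character vector of significant
#'   stable IDs.
#' @param minFractions numeric vector of frequency thresholds
#'   (default `c(0.1, 0.2)`).
#' @param outDir optional directory for TSV/JSON outputs.
#' @return list with `groups`, `frequencies`, `thresholds` (one entry per
#'   fraction), `edges`.
#' @export
runCompare <- function(groupTable, results, minFractions = c(0.1, 0.2),
                       outDir = NULL) {
  if (is.character(groupTable)) groupTable <- .readTsv(groupTable)
  .requireColumns(groupTable, c("drug_id", "group_label"), "group table")
  getSet <- function(d) {
    r <- results[[d]]
    if (is.null(r)) character(0)
    else if (is(r, "EnrichResult")) resultTable(r)$stId
    else as.character(r)
  }
  labels <- sort(unique(groupTable$group_label))
  groups <- lapply(labels, function(lb) {
    ids <- sort(groupTable$drug_id[groupTable$group_label == lb])
    drugGroup(lb, stats::setNames(lapply(ids, getSet), ids))
  })
  names(groups) <- labels
  freqs <- do.call(rbind, c(lapply(groups, pathwayFrequencies),
                            list(make.row.names = FALSE)))
  thresholds <- lapply(minFractions, function(f) thresholdSets(groups, f))
  names(thresholds) <- sprintf("%g", minFractions)
  edges <- bipartiteEdges(groups)
  out <- list(groups = groups, frequencies = freqs,
              thresholds = thresholds, edges = edges)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    .writeTsv(freqs, file.path(outDir, "pathway_frequencies.tsv"))
    .writeTsv(edges, file.path(outDir, "bipartite_edges.tsv"))
    jsonlite::write_json(thresholds,
                         file.path(outDir, "threshold_sets.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
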