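## Source adapters: one per target-database snapshot. Each returns
## list(records, rejects): records are reviewed-human drug-protein links in
## the common TargetRecord layout (drug_id, accession, source, reviewed,
## human, provenance), sorted for byte-stable output; rejects tally every
## skipped row with a reason so one bad row never kills a batch run.

.ORGANISM_CLASSES <- c("human", "mammal_nonhuman", "nonmammal")
.TARGET_TYPES <- c("single_protein", "protein_family", "non_protein")
.EVIDENCE <- c("assay", "mechanism_of_action")

.loadSnapshot <- function(snapshot, cols, what) {
  df <- if (is.data.frame(snapshot)) snapshot else .readTsv(snapshot)
  .requireColumns(df, cols, what)
  df
}

#' Parse a ChEMBL-style activity snapshot into target records
#'
#' Applies the bioactivity filter (assay rows need pChEMBL at or above
#' `pchemblMin`; mechanism-of-action rows qualify without one), drops
#' non-protein and non-mammalian targets, expands protein-family targets to
#' all member accessions, optionally lifts non-human mammalian targets to
#' their human equivalents through the shared gene symbol, and keeps only
#' reviewed human accessions (registry membership, see
#' [reviewedAccessions()]).
#'
#' @param snapshot TSV path or data.frame with columns `drug_id`,
#'   `target_id`, `pchembl`, `organism_class`, `target_type`,
#'   `family_members` (semicolon-joined accessions, may be empty),
#'   `gene_symbol`, `evidence`.
#' @param crossrefs crossref data.frame from [readCrossRef()].
#' @param drugs optional character vector restricting to these ChEMBL IDs.
#' @param pchemblMin inclusive activity threshold on the -log10 molar scale
#'   (default 5, i.e. 10 uM).
#' @param includeOrthologLift lift mammalian non-human targets to human
#'   accessions sharing the gene symbol (default `TRUE`).
#' @return `list(records, rejects)`.
#' @export
parseChemblActivities <- function(snapshot, crossrefs, drugs = NULL,
                                  pchemblMin = 5.0,
                                  includeOrthologLift = TRUE) {
  df <- .loadSnapshot(snapshot,
                      c("drug_id", "target_id", "pchembl", "organism_class",
                        "target_type", "gene_symbol", "evidence"),
                      "chembl snapshot")
  if (!"family_members" %in% names(df)) df$family_members <- ""
  if (!is.null(drugs)) df <- df[df$drug_id %in% drugs, , drop = FALSE]
  registry <- reviewedAccessions(crossrefs)
  rejects <- .emptyRejects()
  recs <- list()

  pch <- suppressWarnings(as.numeric(df$pchembl))
  bad <- !is.na(pch) & (pch < 0 | pch > 14)
  if (any(bad))
    stop("pchembl outside the sane [0, 14] range", call. = FALSE)

  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    p <- pch[i]
    if (!row$evidence %in% .EVIDENCE) {
      rejects <- .addReject(rejects, "chembl", row$drug_id,
                            "unknown-evidence", row$evidence)
      next
    }
    if (!row$organism_class %in% .ORGANISM_CLASSES) {
      rejects <- .addReject(rejects, "chembl", row$drug_id,
                            "unknown-organism-class", row$organism_class)
      next
    }
    if (row$evidence == "assay" && (is.na(p) || p < pchemblMin)) {
      rejects <- .addReject(rejects, "chembl", row$drug_id,
                            "below-threshold", row$target_id)
      next
    }
    if (row$target_type == "non_protein") {
      rejects <- .addReject(rejects, "chembl", row$drug_id,
                            "non-protein-target", row$target_id)
      next
    }
    if (!row$target_type %in% .TARGET_TYPES) {
      rejects <- .addReject(rejects, "chembl", row$drug_id,
                            "unknown-target-type", row$target_type)
      next
    }
    if (row$organism_class == "nonmammal") {
      rejects <- .addReject(rejects, "chembl", row$drug_id,
                            "nonmammal-target", row$target_id)
      next
    }
    if (row$organism_class == "mammal_nonhuman") {
      if (!includeOrthologLift) {
        rejects <- .addReject(rejects, "chembl", row$drug_id,
                              "ortholog-lift-disabled", row$gene_symbol)
        next
      }
      lift <- .geneToAccessions(crossrefs, row$gene_symbol)
      if (nrow(lift) == 0L) {
        rejects <- .addReject(rejects, "chembl", row$drug_id,
                              "no-human-ortholog", row$gene_symbol)
        next
      }
      recs[[length(recs) + 1L]] <- .makeRecords(
        row$drug_id, lift$to_id, "chembl",
        paste0("ortholog-lift:", row$gene_symbol))
      next
    }
    ## human rows
    accs <- if (row$target_type == "protein_family") {
      strsplit(row$family_members, ";", fixed = TRUE)[[1]]
    } else {
      row$target_id
    }
    accs <- accs[nzchar(accs)]
    if (length(accs) == 0L) {
      rejects <- .addReject(rejects, "chembl", row$drug_id,
                            "empty-family", row$target_id)
      next
    }
    ok <- accs %in% registry
    if (any(!ok))
      for (a in accs[!ok])
        rejects <- .addReject(rejects, "chembl", row$drug_id,
                              "unreviewed-accession", a)
    if (any(ok)) {
      prov <- if (row$target_type == "protein_family")
        paste0("family-expansion:", row$target_id) else "assay"
      if (row$evidence == "mechanism_of_action") prov <- "mechanism-of-action"
      recs[[length(recs) + 1L]] <- .makeRecords(row$drug_id, accs[ok],
                                                "chembl", prov)
    }
  }
  records <- if (length(recs) > 0L) do.call(rbind, recs) else .emptyRecords()
  list(records = .sortRecords(records), rejects = rejects)
}

#' Parse a DrugBank-style target snapshot
#'
#' Translates DrugBank compound IDs to ChEMBL IDs via the crossref
#' (many-to-many mappings fan out to one record per mapped ID); accessions
#' not in the reviewed-human registry are rejected.
#'
#' @inheritParams parseChemblActivities
#' @param snapshot TSV path or data.frame with columns `drugbank_id`,
#'   `accession`.
#' @return `list(records, rejects)`.
#' @export
parseDrugbankTargets <- function(snapshot, crossrefs, drugs = NULL) {
  df <- .loadSnapshot(snapshot, c("drugbank_id", "accession"),
                      "drugbank snapshot")
  registry <- reviewedAccessions(crossrefs)
  map <- crossRefLookup(crossrefs, "drugbank", "chembl")
  rejects <- .emptyRejects()
  recs <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    hits <- map$to_id[map$from_id == row$drugbank_id]
    if (length(hits) == 0L) {
      rejects <- .addReject(rejects, "drugbank", row$drugbank_id,
                            "unmapped-drug", row$accession)
      next
    }
    if (length(hits) > 1L)
      warning(sprintf("drugbank %s maps to %d ChEMBL IDs; fanning out",
                      row$drugbank_id, length(hits)), call. = FALSE)
    if (!row$accession %in% registry) {
      rejects <- .addReject(rejects, "drugbank", row$drugbank_id,
                            "unreviewed-accession", row$accession)
      next
    }
    recs[[length(recs) + 1L]] <- .makeRecords(
      hits, row$accession, "drugbank", paste0("drugbank:", row$drugbank_id))
  }
  records <- if (length(recs) > 0L) do.call(rbind, recs) else .emptyRecords()
  if (!is.null(drugs))
    records <- records[records$drug_id %in% drugs, , drop = FALSE]
  list(records = .sortRecords(records), rejects = rejects)
}

#' Parse a TTD-style target snapshot
#'
#' TTD compounds are bridged to ChEMBL through PubChem compound IDs carried
#' in the snapshot, and protein targets arrive as UniProt entry names which
#' are translated to accessions via the crossref.
#'
#' @inheritParams parseChemblActivities
#' @param snapshot TSV path or data.frame with columns `ttd_id`,
#'   `pubchem_cid`, `uniprot_name`.
#' @return `list(records, rejects)`.
#' @export
parseTtdTargets <- function(snapshot, crossrefs, drugs = NULL) {
  df <- .loadSnapshot(snapshot, c("ttd_id", "pubchem_cid", "uniprot_name"),
                      "ttd snapshot")
  cidMap <- crossRefLookup(crossrefs, "pubchem", "chembl")
  nameMap <- crossRefLookup(crossrefs, "uniprot_name", "uniprot_acc")
  registry <- reviewedAccessions(crossrefs)
  rejects <- .emptyRejects()
  recs <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    chembl <- cidMap$to_id[cidMap$from_id == row$pubchem_cid]
    if (length(chembl) == 0L) {
      rejects <- .addReject(rejects, "ttd", row$ttd_id,
                            "unmapped-pubchem-cid", row$pubchem_cid)
      next
    }
    accs <- nameMap$to_id[nameMap$from_id == row$uniprot_name]
    accs <- intersect(accs, registry)
    if (length(accs) == 0L) {
      rejects <- .addReject(rejects, "ttd", row$ttd_id,
                            "untranslatable-uniprot-name", row$uniprot_name)
      next
    }
    for (ch in chembl)
      recs[[length(recs) + 1L]] <- .makeRecords(
        ch, accs, "ttd", paste0("ttd:", row$ttd_id))
  }
  records <- if (length(recs) > 0L) do.call(rbind, recs) else .emptyRecords()
  if (!is.null(drugs))
    records <- records[records$drug_id %in% drugs, , drop = FALSE]
  list(records = .sortRecords(records), rejects = rejects)
}

#' Parse a PharmGKB-style drug-gene relationship snapshot
#'
#' PharmGKB compound IDs translate directly to ChEMBL via the crossref; the
#' target gene symbols resolve to the reviewed human accessions they
#' express (a gene with several reviewed accessions emits all of them).
#'
#' @inheritParams parseChemblActivities
#' @param snapshot TSV path or data.frame with columns `pharmgkb_id`,
#'   `gene_symbol`.
#' @return `list(records, rejects)`.
#' @export
parsePharmgkbTargets <- function(snapshot, crossrefs, drugs = NULL) {
  df <- .loadSnapshot(snapshot, c("pharmgkb_id", "gene_symbol"),
                      "pharmgkb snapshot")
  drugMap <- crossRefLookup(crossrefs, "pharmgkb", "chembl")
  rejects <- .emptyRejects()
  recs <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    chembl <- drugMap$to_id[drugMap$from_id == row$pharmgkb_id]
    if (length(chembl) == 0L) {
      rejects <- .addReject(rejects, "pharmgkb", row$pharmgkb_id,
                            "unmapped-drug", row$gene_symbol)
      next
    }
    accs <- .geneToAccessions(crossrefs, row$gene_symbol)$to_id
    if (length(accs) == 0L) {
      rejects <- .addReject(rejects, "pharmgkb", row$pharmgkb_id,
                            "unmapped-gene", row$gene_symbol)
      next
    }
    for (ch in chembl)
      recs[[length(recs) + 1L]] <- .makeRecords(
        ch, accs, "pharmgkb", paste0("gene:", row$gene_symbol))
  }
  records <- if (length(recs) > 0L) do.call(rbind, recs) else .emptyRecords()
  if (!is.null(drugs))
    records <- records[records$drug_id %in% drugs, , drop = FALSE]
  list(records = .sortRecords(records), rejects = rejects)
}

#' Parse an IUPHAR/Guide-to-Pharmacology-style ligand-target snapshot
#'
#' IUPHAR uses one target identifier across organisms, so each target ID is
#' resolved to the human UniProt accession only (crossref namespace
#' `iuphar_target`); ligands map back to ChEMBL via `iuphar_ligand` rows.
#' Targets with no human equivalent are skipped and counted.
#'
#' @inheritParams parseChemblActivities
#' @param snapshot TSV path or data.frame with columns `ligand_id`,
#'   `target_id`.
#' @return `list(records, rejects)`.
#' @export
parseIupharTargets <- function(snapshot, crossrefs, drugs = NULL) {
  df <- .loadSnapshot(snapshot, c("ligand_id", "target_id"),
                      "iuphar snapshot")
  ligMap <- crossRefLookup(crossrefs, "iuphar_ligand", "chembl")
  tgtMap <- crossRefLookup(crossrefs, "iuphar_target", "uniprot_acc")
  registry <- reviewedAccessions(crossrefs)
  rejects <- .emptyRejects()
  recs <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    chembl <- ligMap$to_id[ligMap$from_id == row$ligand_id]
    if (length(chembl) == 0L) {
      rejects <- .addReject(rejects, "iuphar", row$ligand_id,
                            "unmapped-ligand", row$target_id)
      next
    }
    accs <- tgtMap$to_id[tgtMap$from_id == row$target_id]
    accs <- intersect(accs, registry)
    if (length(accs) == 0L) {
      rejects <- .addReject(rejects, "iuphar", row$ligand_id,
                            "no-human-equivalent", row$target_id)
      next
    }
    for (ch in chembl)
      recs[[length(recs) + 1L]] <- .makeRecords(
        ch, accs, "iuphar", paste0("iuphar-target:", row$target_id))
  }
  records <- if (length(recs) > 0L) do.call(rbind, recs) else .emptyRecords()
  if (!is.null(drugs))
    records <- records[records$drug_id %in% drugs, , drop = FALSE]
  list(records = .sortRecords(records), rejects = rejects)
}
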