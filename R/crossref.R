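#' Read an identifier cross-reference table
#'
#' The cross-reference table is a four-column TSV
#' (`namespace_a`, `id_a`, `namespace_b`, `id_b`) holding every identifier
#' bridge the adapters need: ChEMBL to DrugBank / PubChem / PharmGKB /
#' IUPHAR-ligand compound links, UniProt entry name to accession, accession
#' to gene symbol, IUPHAR target to human accession, and ChEBI to ChEMBL for
#' reference edge lists. Many-to-many rows are permitted; exact duplicate
#' rows are not.
#'
#' @param path TSV file path, or a data.frame already in the four-column
#'   layout.
#' @return data.frame with the four columns, duplicates rejected.
#' @export
readCrossRef <- function(path) {
  xref <- if (is.data.frame(path)) path else .readTsv(path)
  .requireColumns(xref, c("namespace_a", "id_a", "namespace_b", "id_b"),
                  "crossref")
  if (anyDuplicated(xref[c("namespace_a", "id_a", "namespace_b", "id_b")]))
    stop("crossref contains duplicate rows", call. = FALSE)
  xref
}

#' Look up identifier mappings in a cross-reference table
#'
#' Directionless lookup: a row matches whether the (from, to) namespaces
#' appear as (a, b) or (b, a). Many-to-many mappings return one row per
#' mapped pair.
#'
#' @param xref crossref data.frame from [readCrossRef()].
#' @param from,to namespace names, e.g. `"drugbank"`, `"chembl"`.
#' @param ids optional character vector restricting the `from` side.
#' @return data.frame with columns `from_id`, `to_id`.
#' @export
crossRefLookup <- function(xref, from, to, ids = NULL) {
  if (nrow(xref) == 0L)
    stop("configuration error: empty crossref table", call. = FALSE)
  fwd <- xref$namespace_a == from & xref$namespace_b == to
  rev <- xref$namespace_a == to & xref$namespace_b == from
  out <- rbind(
    data.frame(from_id = xref$id_a[fwd], to_id = xref$id_b[fwd],
               stringsAsFactors = FALSE),
    data.frame(from_id = xref$id_b[rev], to_id = xref$id_a[rev],
               stringsAsFactors = FALSE)
  )
  out <- unique(out)
  if (!is.null(ids)) out <- out[out$from_id %in% ids, , drop = FALSE]
  o <- order(out$from_id, out$to_id, method = "radix")
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reviewed human accession registry
#'
#' The accession-to-gene-symbol block of the cross-reference doubles as the
#' registry of reviewed (manually curated) human UniProt entries: only such
#' entries are listed there, so membership is the reviewed-human check
#' applied by every source adapter.
#'
#' @param xref crossref data.frame.
#' @return character vector of reviewed human accessions.
#' @export
reviewedAccessions <- function(xref) {
  map <- crossRefLookup(xref, "uniprot_acc", "gene_symbol")
  sort(unique(map$from_id))
}

## gene symbol -> reviewed human accession(s)
.geneToAccessions <- function(xref, genes = NULL) {
  crossRefLookup(xref, "gene_symbol", "uniprot_acc", ids = genes)
}

## accession -> gene symbol(s)
.accessionToGenes <- function(xref, accs = NULL) {
  crossRefLookup(xref, "uniprot_acc", "gene_symbol", ids = accs)
}
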