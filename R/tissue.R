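#' Read a consensus tissue expression table
#'
#' Long-format TSV with one row per (gene, tissue): columns `gene_symbol`,
#' `tissue`, `ntpm` (consensus normalized transcripts per million).
#'
#' @param path TSV path or a data.frame in that layout.
#' @return data.frame with `ntpm` numeric.
#' @export
readExpression <- function(path) {
  df <- if (is.data.frame(path)) path else .readTsv(path)
  .requireColumns(df, c("gene_symbol", "tissue", "ntpm"), "expression table")
  df$ntpm <- as.numeric(df$ntpm)
  if (any(is.na(df$ntpm)) || any(df$ntpm < 0))
    stop("schema error in expression table: ntpm must be numeric and >= 0",
         call. = FALSE)
  if (anyDuplicated(df[c("gene_symbol", "tissue")]))
    stop("schema error in expression table: duplicate (gene, tissue) rows",
         call. = FALSE)
  df
}

#' Restrict target profiles to proteins expressed in a tissue
#'
#' Keeps an accession when any gene symbol it maps to has consensus
#' expression of at least `minNtpm` in the chosen tissue. Accessions whose
#' gene is absent from the expression table (or that map to no gene) are
#' kept only with `keepUnmeasured = TRUE`; otherwise they are dropped and
#' counted. Filtering is idempotent and antitone in the threshold.
#'
#' @param profiles a \linkS4class{TargetProfiles}.
#' @param expression expression data.frame from [readExpression()].
#' @param crossrefs crossref data.frame carrying accession-to-gene rows.
#' @param tissue tissue name; must exist in the expression table.
#' @param minNtpm inclusive expression threshold in nTPM (default 1.0, the
#'   usual "not detected below 1 nTPM" convention for consensus data).
#' @param keepUnmeasured keep accessions with no expression evidence
#'   (default `FALSE`).
#' @return a \linkS4class{TargetProfiles}; drop counts are in
#'   `object@metadata$tissueFilter`.
#' @export
filterProfiles <- function(profiles, expression, crossrefs, tissue,
                           minNtpm = 1.0, keepUnmeasured = FALSE) {
  stopifnot(is(profiles, "TargetProfiles"), minNtpm > 0)
  expression <- readExpression(expression)
  tissues <- sort(unique(expression$tissue))
  if (!tissue %in% tissues)
    stop(sprintf("unknown tissue '%s'; available: %s", tissue,
                 paste(tissues, collapse = ", ")), call. = FALSE)
  pairs <- profileTable(profiles)
  if (nrow(pairs) == 0L) return(profiles)

  acc2gene <- .accessionToGenes(crossrefs, unique(pairs$accession))
  expr <- expression[expression$tissue == tissue, , drop = FALSE]
  ntpm <- stats::setNames(expr$ntpm, expr$gene_symbol)

  keep <- logical(nrow(pairs))
  nUnmeasured <- 0L
  nBelow <- 0L
  for (i in seq_len(nrow(pairs))) {
    genes <- acc2gene$to_id[acc2gene$from_id == pairs$accession[i]]
    measured <- genes[genes %in% names(ntpm)]
    if (length(measured) == 0L) {
      keep[i] <- keepUnmeasured
      nUnmeasured <- nUnmeasured + 1L
    } else if (any(ntpm[measured] >= minNtpm)) {
      keep[i] <- TRUE
    } else {
      nBelow <- nBelow + 1L
    }
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  md <- profiles@metadata
  md$tissueFilter <- list(tissue = tissue, minNtpm = minNtpm,
                          keepUnmeasured = keepUnmeasured,
                          removedBelowThreshold = nBelow,
                          unmeasured = nUnmeasured,
                          kept = nrow(out))
  new("TargetProfiles", pairs = out, metadata = md)
}
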