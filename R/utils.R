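## Internal helpers shared across modules.

.readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

## Fixed-format number rendering so repeated runs are byte-identical.
.fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.10g", v)
  }, character(1))
  out
}

.requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stop(sprintf("schema error in %s: missing column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

## Deterministic 31-bit seed for a labeled substream, so each generated
## file draws from its own stream and adding a file never perturbs others.
.labelSeed <- function(seed, label) {
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

.emptyRecords <- function() {
  data.frame(drug_id = character(), accession = character(),
             source = character(), reviewed = logical(), human = logical(),
             provenance = character(), stringsAsFactors = FALSE)
}

.emptyRejects <- function() {
  data.frame(source = character(), drug_id = character(),
             reason = character(), detail = character(),
             stringsAsFactors = FALSE)
}

.sortRecords <- function(records) {
  if (nrow(records) == 0L) return(records)
  o <- order(records$drug_id, records$accession, records$source,
             records$provenance, method = "radix")
  rec <- records[o, , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

.makeRecords <- function(drug_id, accession, source, provenance) {
  data.frame(drug_id = drug_id, accession = accession, source = source,
             reviewed = TRUE, human = TRUE, provenance = provenance,
             stringsAsFactors = FALSE)
}

.addReject <- function(rejects, source, drug_id, reason, detail) {
  rbind(rejects, data.frame(source = source, drug_id = drug_id,
                            reason = reason, detail = detail,
                            stringsAsFactors = FALSE))
}
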