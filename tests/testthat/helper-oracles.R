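## Independent oracles used across the suite.

## Exhaustive enumeration of the hypergeometric upper tail: label the K
## pathway members 1..K in a universe 1..N, enumerate every C(N, n) draw,
## and count draws containing at least k members. Only usable where the
## draw count is enumerable.
enumUpperTail <- function(k, K, n, N) {
  stopifnot(choose(N, n) <= 2e5)
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)
  sum(hits >= k) / ncol(draws)
}

## Literal Benjamini-Hochberg step-up rule: adj_(i) = min_{j >= i}
## p_(j) * m / j, clipped at 1, mapped back to input order. Deliberately
## written as a double loop, independent of the implementation.
bhOracle <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in i:n) best <- min(best, sorted[j] * m / j)
    adj[i] <- min(1, best)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

## Minimal crossref with a reviewed-human registry for the given
## accession -> gene map, plus any extra rows.
makeXref <- function(acc2gene, extra = NULL) {
  xr <- data.frame(namespace_a = "uniprot_acc", id_a = names(acc2gene),
                   namespace_b = "gene_symbol", id_b = unname(acc2gene),
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) xr <- rbind(xr, extra)
  xr
}

xrefRow <- function(na, ia, nb, ib) {
  data.frame(namespace_a = na, id_a = ia, namespace_b = nb, id_b = ib,
             stringsAsFactors = FALSE)
}

## ChEMBL snapshot row builder with sane defaults.
chemblRow <- function(drug, target, pchembl = "7.00",
                      organism = "human", type = "single_protein",
                      family = "", gene = "", evidence = "assay") {
  data.frame(drug_id = drug, target_id = target, pchembl = pchembl,
             organism_class = organism, target_type = type,
             family_members = family, gene_symbol = gene,
             evidence = evidence, stringsAsFactors = FALSE)
}

microDir <- function() system.file("extdata", "micro", package = "drugpath")
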