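makePathways <- function(ids, names, members, disease = NULL) {
  if (is.null(disease)) disease <- rep(FALSE, length(ids))
  new("PathwaySet", stId = ids, name = names,
      members = stats::setNames(members, ids), isDisease = disease,
      taxId = rep(9606L, length(ids)))
}

test_that("hypergeometric upper tail handles the degenerate cases", {
  expect_equal(hypergeomUpperTail(0, 4, 5, 10), 1)
  expect_equal(hypergeomUpperTail(3, 10, 3, 10), 1)
  ## worked case: 66 of the 252 equally likely draws have >= 3 members
  expect_equal(hypergeomUpperTail(3, 4, 5, 10), 66 / 252, tolerance = 1e-14)
  expect_error(hypergeomUpperTail(5, 4, 4, 10), "domain error")
  expect_error(hypergeomUpperTail(1, 11, 5, 10), "domain error")
})

test_that("upper tail matches enumeration and the survival function", {
  set.seed(101)
  for (i in 1:40) {
    N <- sample(6:25, 1)
    K <- sample(1:N, 1)
    n <- sample(1:min(N, 8), 1)
    k <- sample(0:min(n, K), 1)
    if (choose(N, n) > 2e5) next
    p <- hypergeomUpperTail(k, K, n, N)
    expect_equal(p, enumUpperTail(k, K, n, N), tolerance = 1e-12)
    expect_equal(p, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("upper tail stays accurate on large universes", {
  ## independent check against the survival function at N = 10^4
  p <- hypergeomUpperTail(8, 50, 10, 10000)
  expect_equal(p, stats::phyper(7, 50, 9950, 10, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_gt(p, 0)
})

test_that("BH adjustment reproduces the hand-applied step-up rule", {
  expect_equal(bhAdjust(c(0.001, 0.01, 0.03, 0.04)),
               c(0.004, 0.02, 0.04, 0.04))
  expect_equal(bhAdjust(0.123), 0.123)
  expect_equal(bhAdjust(rep(0.02, 5)), rep(0.02, 5))
})

test_that("BH matches the literal oracle and p.adjust on random vectors", {
  set.seed(77)
  for (i in 1:25) {
    len <- sample(c(1:5, 20, 100), 1)
    p <- round(runif(len, 1e-6, 1), sample(c(2, 6), 1))  # rounding => ties
    p[p == 0] <- 1e-6
    adj <- bhAdjust(p)
    expect_equal(adj, bhOracle(p), tolerance = 1e-12)
    expect_equal(adj, stats::p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("pathway depths follow shortest paths from the roots", {
  h <- new("PathwayHierarchy", parent = c("A", "B"), child = c("B", "C"))
  d <- pathwayDepths(h)
  expect_equal(d[["A"]], 0)
  expect_equal(d[["B"]], 1)
  expect_equal(d[["C"]], 2)
  ## chain with minDepth 2: only the leaf survives
  expect_equal(pruneHighLevel(c("A", "B", "C"), h, minDepth = 2L), "C")
  expect_equal(pruneHighLevel(c("A", "B", "C"), h, minDepth = 0L),
               c("A", "B", "C"))
  expect_equal(pruneHighLevel(c("A", "B", "C"), h, minDepth = 1L),
               c("B", "C"))
  expect_warning(kept <- pruneHighLevel(c("A", "X"), h, minDepth = 1L),
                 "missing from the hierarchy")
  expect_equal(kept, "X")
  expect_error(new("PathwayHierarchy", parent = c("A", "B"),
                   child = c("B", "A")), "cycle")
})

oraFixture <- function() {
  ## universe of 8 accessions in 3 non-disease leaf pathways under a root
  accs <- sprintf("P1000%d", 1:8)
  pws <- makePathways(
    c("R-HSA-1", "R-HSA-2", "R-HSA-3", "R-HSA-9"),
    c("Leaf one", "Leaf two", "Leaf three", "Root"),
    list(accs[1:3], accs[4:6], accs[6:8], accs))
  h <- new("PathwayHierarchy", parent = rep("R-HSA-9", 3),
           child = c("R-HSA-1", "R-HSA-2", "R-HSA-3"))
  list(accs = accs, pws = pws, h = h)
}

test_that("a drug whose targets fill one small pathway ranks it first", {
  fx <- oraFixture()
  res <- runOra(fx$accs[1:3], fx$pws, fx$h, drug = "CHEMBLX")
  tab <- resultTable(res)
  ## oracle: hand-enumerated tails with m = 2 tested pathways
  ## p(leaf one) = 1/C(8,3) = 1/56; BH adj = 2/56 = 1/28
  expect_equal(tab$stId[1], "R-HSA-1")
  expect_equal(tab$pValue[1], 1 / 56, tolerance = 1e-12)
  expect_equal(tab$fdr[1], 1 / 28, tolerance = 1e-12)
  expect_equal(res@nTested, 2L)       # root tested, zero-overlap leaves not
  expect_equal(nrow(tab), 1L)         # root pruned (depth 0) and fdr = 1
})

test_that("profiles disjoint from all pathways give a status, not an error", {
  fx <- oraFixture()
  res <- runOra(c("Q99999", "Q99998"), fx$pws, fx$h)
  expect_equal(enrichStatus(res), "no-proteins-found")
  expect_equal(nrow(resultTable(res)), 0L)
})

test_that("zero-overlap pathways do not enter the BH family", {
  fx <- oraFixture()
  base <- runOra(fx$accs[1:3], fx$pws, fx$h, fdrCutoff = 1, minDepth = 0L)
  ## add a pathway with zero overlap whose members are already in the
  ## universe: no reported p or fdr may change
  pws2 <- makePathways(
    c(fx$pws@stId, "R-HSA-4"), c(fx$pws@name, "Zero overlap"),
    c(fx$pws@members, list(fx$accs[7:8])))
  again <- runOra(fx$accs[1:3], pws2, fx$h, fdrCutoff = 1, minDepth = 0L)
  b <- resultTable(base)
  a <- resultTable(again)
  expect_identical(a[c("stId", "pValue", "fdr")],
                   b[c("stId", "pValue", "fdr")])
  expect_equal(again@nTested, base@nTested)
})

test_that("disease pathways are excluded from test and universe", {
  accs <- sprintf("P1000%d", 1:6)
  pws <- makePathways(c("R-HSA-1", "R-HSA-2"),
                      c("Healthy", "Disease"),
                      list(accs[1:3], accs[4:6]),
                      disease = c(FALSE, TRUE))
  res <- runOra(accs[1:3], pws, NULL, fdrCutoff = 1)
  expect_equal(res@universeSize, 3L)
  expect_false("R-HSA-2" %in% resultTable(res)$stId)
  withDis <- runOra(accs[1:3], pws, NULL, fdrCutoff = 1,
                    excludeDisease = FALSE)
  expect_equal(withDis@universeSize, 6L)
})

test_that("results at a stricter FDR cutoff are a subset of the looser one", {
  set.seed(5)
  accs <- sprintf("P1%04d", 1:60)
  pws <- makePathways(sprintf("R-HSA-%d", 1:12),
                      sprintf("Pathway %d", 1:12),
                      lapply(1:12, function(i) sample(accs, 8)))
  profile <- sample(accs, 10)
  strict <- resultTable(runOra(profile, pws, NULL, fdrCutoff = 0.01))$stId
  loose <- resultTable(runOra(profile, pws, NULL, fdrCutoff = 0.05))$stId
  expect_true(all(strict %in% loose))
})
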