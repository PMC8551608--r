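test_that("affected-compound fractions match a hand count", {
  results <- stats::setNames(lapply(1:10, function(i) {
    if (i <= 4) c("R-HSA-X", sprintf("R-HSA-%d", i))
    else sprintf("R-HSA-%d", i)
  }), sprintf("CHEMBL%d", 1:10))
  g <- drugGroup("toxic", results)
  fr <- pathwayFrequencies(g)
  ## pathway X hit by 4 of 10 drugs -> 0.4
  expect_equal(fr$fraction[fr$st_id == "R-HSA-X"], 0.4)
  expect_equal(fr$n_group[1], 10L)
  ## single drug: every pathway at fraction 1
  g1 <- drugGroup("solo", list(CHEMBL99 = c("A", "B", "C")))
  expect_equal(pathwayFrequencies(g1)$fraction, rep(1, 3))
})

test_that("empty drugs are excluded from the frequency denominator", {
  g <- drugGroup("mix", list(CHEMBL1 = c("A"), CHEMBL2 = character(0)))
  fr <- pathwayFrequencies(g)
  expect_equal(fr$n_group, 1L)
  expect_equal(attr(fr, "n_empty_drugs"), 1L)
  gAllEmpty <- drugGroup("none", list(CHEMBL1 = character(0)))
  expect_error(pathwayFrequencies(gAllEmpty), "no drugs with significant")
})

test_that("threshold sets recover a planted two-group overlap", {
  ## planted design: 3 pathways shared at >= 20% of both groups
  shared <- sprintf("R-HSA-S%d", 1:3)
  gA <- drugGroup("cardiotoxic", stats::setNames(lapply(1:10, function(i)
    c(if (i <= 2) shared else character(0), sprintf("R-HSA-A%d", i))),
    sprintf("CHEMBLA%d", 1:10)))
  gB <- drugGroup("therapy", stats::setNames(lapply(1:10, function(i)
    c(if (i <= 2) shared else character(0), sprintf("R-HSA-B%d", i))),
    sprintf("CHEMBLB%d", 1:10)))
  ts <- thresholdSets(list(gA, gB), 0.2)
  expect_equal(ts$intersections[["cardiotoxic|therapy"]], sort(shared))
  expect_false(any(shared %in% ts$exclusive$cardiotoxic))
  ## identical groups leave nothing exclusive
  ts2 <- thresholdSets(list(gA, drugGroup("copy", gA$results)), 0.2)
  expect_equal(lengths(ts2$exclusive), c(cardiotoxic = 0L, copy = 0L))
})

test_that("threshold sets are antitone in the fraction", {
  set.seed(12)
  g <- drugGroup("grp", stats::setNames(lapply(1:12, function(i)
    sample(sprintf("R-HSA-%d", 1:15), sample(1:6, 1))),
    sprintf("CHEMBL%d", 1:12)))
  s10 <- thresholdSets(list(g), 0.1)$sets$grp
  s20 <- thresholdSets(list(g), 0.2)$sets$grp
  sEps <- thresholdSets(list(g), 1e-9)$sets$grp
  expect_true(all(s20 %in% s10))
  expect_setequal(sEps, unique(unlist(g$results)))
})

test_that("bipartite edges count one edge per group occurrence", {
  gA <- drugGroup("a", list(CHEMBL1 = c("X", "Y"), CHEMBL2 = "X"))
  gB <- drugGroup("b", list(CHEMBL1 = "X"))
  edges <- bipartiteEdges(list(gA, gB))
  expect_equal(nrow(edges), 4L)  # hand count: 3 in a + 1 in b
  expect_equal(sum(edges$group == "a"),
               sum(lengths(gA$results)))
  empty <- bipartiteEdges(list(drugGroup("e", list(CHEMBL9 =
                                                     character(0)))))
  expect_equal(nrow(empty), 0L)
  ## order invariance
  gA2 <- drugGroup("a", gA$results[c(2, 1)])
  expect_identical(bipartiteEdges(list(gB, gA2)), edges)
})

test_that("novelty report partitions discovered and reference edges", {
  discovered <- list(CHEMBL1 = sprintf("R-HSA-%d", 1:5))
  reference <- data.frame(drug_id = "CHEMBL1",
                          st_id = sprintf("R-HSA-%d", 4:6),
                          stringsAsFactors = FALSE)
  rep1 <- noveltyVsReference(discovered, reference)
  ## fixture: 5 discovered, 3 referenced, overlap 2 -> (2, 3, 1)
  expect_equal(unlist(rep1$per_drug[c("recovered", "novel", "missed")]),
               c(recovered = 2L, novel = 3L, missed = 1L))
  ## partition identities
  expect_equal(rep1$per_drug$recovered + rep1$per_drug$novel,
               length(discovered$CHEMBL1))
  ## empty reference: everything novel
  rep2 <- noveltyVsReference(discovered,
                             reference[0, ])
  expect_equal(rep2$overall$novel, 5L)
  expect_equal(rep2$overall$recovered, 0L)
  ## discovered == reference: no novel, no missed
  rep3 <- noveltyVsReference(list(CHEMBL1 = sprintf("R-HSA-%d", 4:6)),
                             reference)
  expect_equal(rep3$overall$novel, 0L)
  expect_equal(rep3$overall$missed, 0L)
})
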