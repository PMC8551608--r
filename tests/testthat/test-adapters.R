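xref <- makeXref(
  c(P10001 = "ALPHA", P10002 = "BETA", P10003 = "GAMMA", P21964 = "COMT"))

test_that("ChEMBL assay filter is inclusive at the pChEMBL threshold", {
  snap <- rbind(
    chemblRow("CHEMBL1", "P10001", pchembl = "4.90", gene = "ALPHA"),
    chemblRow("CHEMBL1", "P10002", pchembl = "5.00", gene = "BETA"),
    chemblRow("CHEMBL1", "P10003", pchembl = "5.01", gene = "GAMMA"))
  out <- parseChemblActivities(snap, xref)
  expect_setequal(out$records$accession, c("P10002", "P10003"))
  expect_equal(out$rejects$reason, "below-threshold")
})

test_that("mechanism-of-action rows qualify without a pChEMBL value", {
  snap <- chemblRow("CHEMBL1", "P10001", pchembl = "", gene = "ALPHA",
                    evidence = "mechanism_of_action")
  out <- parseChemblActivities(snap, xref)
  expect_equal(out$records$accession, "P10001")
})

test_that("protein families expand to every member accession", {
  snap <- chemblRow("CHEMBL1", "FAM1", pchembl = "7.00",
                    type = "protein_family",
                    family = "P10001;P10002;P10003")
  out <- parseChemblActivities(snap, xref)
  expect_equal(nrow(out$records), 3L)
  expect_setequal(out$records$accession, c("P10001", "P10002", "P10003"))
  expect_true(all(grepl("family-expansion", out$records$provenance)))
})

test_that("mammalian targets lift to the human accession via gene symbol", {
  ## oracle: manual join of the rat row's gene symbol against the registry
  snap <- chemblRow("CHEMBL1", "RAT-Comt", pchembl = "6.20",
                    organism = "mammal_nonhuman", gene = "COMT")
  out <- parseChemblActivities(snap, xref)
  expect_equal(out$records$accession, "P21964")
  expect_match(out$records$provenance, "ortholog-lift")
  ## disabling the lift yields a subset of the enabled run
  off <- parseChemblActivities(snap, xref, includeOrthologLift = FALSE)
  expect_equal(nrow(off$records), 0L)
  expect_equal(off$rejects$reason, "ortholog-lift-disabled")
})

test_that("non-protein, non-mammalian and unreviewed targets are rejected", {
  snap <- rbind(
    chemblRow("CHEMBL1", "CHEBI:99", type = "non_protein"),
    chemblRow("CHEMBL1", "ZFIN-1", organism = "nonmammal", gene = "ALPHA"),
    chemblRow("CHEMBL1", "Q99999", gene = "DECOY"))
  out <- parseChemblActivities(snap, xref)
  expect_equal(nrow(out$records), 0L)
  expect_setequal(out$rejects$reason,
                  c("non-protein-target", "nonmammal-target",
                    "unreviewed-accession"))
})

test_that("schema violations fail loudly, bad organism rows are collected", {
  snap <- chemblRow("CHEMBL1", "P10001", gene = "ALPHA")
  expect_error(parseChemblActivities(snap[, -3], xref), "pchembl")
  odd <- chemblRow("CHEMBL1", "P10001", organism = "martian",
                   gene = "ALPHA")
  out <- parseChemblActivities(rbind(snap, odd), xref)
  expect_equal(nrow(out$records), 1L)
  expect_equal(out$rejects$reason, "unknown-organism-class")
})

test_that("lowering the pChEMBL threshold never removes records", {
  set.seed(42)
  snap <- do.call(rbind, lapply(1:30, function(i)
    chemblRow(sprintf("CHEMBL%d", sample(3, 1)),
              sample(c("P10001", "P10002", "P10003"), 1),
              pchembl = sprintf("%.2f", runif(1, 3, 9)),
              gene = "ALPHA")))
  key <- function(res) paste(res$records$drug_id, res$records$accession,
                             res$records$provenance)
  thresholds <- c(7, 6, 5, 4)
  sets <- lapply(thresholds, function(t)
    key(parseChemblActivities(snap, xref, pchemblMin = t)))
  for (i in seq_len(length(sets) - 1L))
    expect_true(all(sets[[i]] %in% sets[[i + 1L]]))
})

test_that("DrugBank IDs translate to ChEMBL with many-to-many fan-out", {
  extra <- rbind(xrefRow("drugbank", "DB00001", "chembl", "CHEMBL1"),
                 xrefRow("drugbank", "DB00002", "chembl", "CHEMBL2"),
                 xrefRow("drugbank", "DB00002", "chembl", "CHEMBL3"))
  xr <- makeXref(c(P10001 = "ALPHA", P10002 = "BETA"), extra)
  snap <- data.frame(drugbank_id = c("DB00001", "DB00001", "DB00002",
                                     "DB00404"),
                     accession = c("P10001", "P10002", "P10001", "P10001"),
                     stringsAsFactors = FALSE)
  out <- suppressWarnings(parseDrugbankTargets(snap, xr))
  ## oracle: hand cross-join -> DB00001 gives 2 records, DB00002 fans out
  ## to 2 ChEMBL IDs, DB00404 is unmapped
  expect_equal(nrow(out$records), 4L)
  expect_setequal(out$records$drug_id[out$records$accession == "P10001"],
                  c("CHEMBL1", "CHEMBL2", "CHEMBL3"))
  expect_equal(sum(out$rejects$reason == "unmapped-drug"), 1L)
  expect_error(parseDrugbankTargets(snap, xr[0, ]), "empty crossref")
})

test_that("TTD resolves drugs via PubChem and targets via UniProt names", {
  extra <- rbind(xrefRow("pubchem", "123", "chembl", "CHEMBLY"),
                 xrefRow("uniprot_name", "COMT_HUMAN", "uniprot_acc",
                         "P21964"))
  xr <- makeXref(c(P21964 = "COMT"), extra)
  snap <- data.frame(
    ttd_id = c("D00ABC", "D00ABD", "D00ABE"),
    pubchem_cid = c("123", "123", "999"),
    uniprot_name = c("COMT_HUMAN", "GHOST_HUMAN", "COMT_HUMAN"),
    stringsAsFactors = FALSE)
  out <- parseTtdTargets(snap, xr)
  ## oracle: two-step join by hand -> only the first row survives
  expect_equal(out$records$drug_id, "CHEMBLY")
  expect_equal(out$records$accession, "P21964")
  expect_setequal(out$rejects$reason,
                  c("untranslatable-uniprot-name", "unmapped-pubchem-cid"))
})

test_that("PharmGKB genes resolve to all reviewed accessions they express", {
  extra <- rbind(xrefRow("pharmgkb", "PA001", "chembl", "CHEMBL1"),
                 xrefRow("uniprot_acc", "P10009", "gene_symbol", "MULTI"))
  xr <- makeXref(c(P10001 = "MULTI", P10002 = "BETA"), extra)
  snap <- data.frame(pharmgkb_id = c("PA001", "PA001", "PA404"),
                     gene_symbol = c("MULTI", "GHOST", "BETA"),
                     stringsAsFactors = FALSE)
  out <- parsePharmgkbTargets(snap, xr)
  ## oracle: manual join; MULTI maps to two reviewed accessions
  expect_setequal(out$records$accession, c("P10001", "P10009"))
  expect_setequal(out$rejects$reason, c("unmapped-gene", "unmapped-drug"))
})

test_that("IUPHAR organism-agnostic targets resolve to human only", {
  extra <- rbind(xrefRow("iuphar_ligand", "555", "chembl", "CHEMBL1"),
                 xrefRow("iuphar_target", "2472", "uniprot_acc", "P21964"))
  xr <- makeXref(c(P21964 = "COMT"), extra)
  snap <- data.frame(ligand_id = c("555", "555", "555"),
                     target_id = c("2472", "2472", "9999"),
                     stringsAsFactors = FALSE)
  out <- parseIupharTargets(snap, xr)
  ## duplicate ligand rows stay duplicated here; harmonization dedups
  expect_equal(out$records$accession, c("P21964", "P21964"))
  expect_equal(out$rejects$reason, "no-human-equivalent")
  profiles <- buildProfiles(out$records)
  expect_equal(profileAccessions(profiles, "CHEMBL1"), "P21964")
})

test_that("adapters are deterministic and emit only reviewed human records", {
  u <- generateUniverse(simulationConfig(seed = 31, nProteins = 120L,
                                         nPathways = 12L, nDrugs = 8L,
                                         nPlantedDrugs = 4L))
  run <- function() {
    parts <- list(
      parseChemblActivities(u$snapshots$chembl, u$crossref),
      parseDrugbankTargets(u$snapshots$drugbank, u$crossref),
      parseTtdTargets(u$snapshots$ttd, u$crossref),
      parsePharmgkbTargets(u$snapshots$pharmgkb, u$crossref),
      parseIupharTargets(u$snapshots$iuphar, u$crossref))
    do.call(rbind, lapply(parts, `[[`, "records"))
  }
  r1 <- run()
  r2 <- run()
  expect_identical(r1, r2)
  expect_true(all(r1$reviewed) && all(r1$human))
  expect_true(all(isUniprotAccession(r1$accession)))
})
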