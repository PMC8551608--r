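#' Configuration for the synthetic snapshot universe
#'
#' Defines a miniature, fully offline stand-in for the five target-database
#' snapshots, the identifier cross-reference, the tissue expression table
#' and the pathway annotation/hierarchy files, with planted drug-to-pathway
#' enrichment as recoverable ground truth. The seed fully determines every
#' output.
#'
#' @param seed master RNG seed; labeled substreams are derived from it per
#'   output file so adding a file never perturbs the others.
#' @param nProteins universe size (default 1000).
#' @param nPathways number of leaf pathways (default 100); a 3-level
#'   hierarchy (roots, mid-level, leaves) is built above them.
#' @param pathwaySizeRange inclusive (min, max) leaf pathway sizes
#'   (default 5-50).
#' @param nDrugs number of drugs (default 50).
#' @param targetsPerDrug targets drawn per drug (default 10).
#' @param plantedFraction share of a planted drug's targets drawn from its
#'   assigned pathway (default 0.8).
#' @param nPlantedDrugs number of drugs with a planted pathway (default 20).
#' @param tissues tissue names for the expression table.
#' @param expressedFraction per-tissue fraction of genes expressed
#'   (default 0.6); expressed genes get lognormal nTPM around 20, the rest
#'   uniform below 0.9, and 5% of genes have no row at all (unmeasured).
#' @param sourceRedundancy probability a true drug-target pair is deposited
#'   in a second source snapshot as well (default 0.5).
#' @param pchemblQualifying,pchemblNonQualifying `c(mean, sd)` of the normal
#'   draws for qualifying (clamped at >= 5) and sub-threshold (clamped
#'   below 5) assay pChEMBL values.
#' @return validated `SimulationConfig` list.
#' @export
simulationConfig <- function(seed,
                             nProteins = 1000L,
                             nPathways = 100L,
                             pathwaySizeRange = c(5L, 50L),
                             nDrugs = 50L,
                             targetsPerDrug = 10L,
                             plantedFraction = 0.8,
                             nPlantedDrugs = 20L,
                             tissues = c("heart", "liver"),
                             expressedFraction = 0.6,
                             sourceRedundancy = 0.5,
                             pchemblQualifying = c(mean = 7, sd = 0.8),
                             pchemblNonQualifying = c(mean = 4.2, sd = 0.4)) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            nProteins >= 10L, nPathways >= 1L,
            length(pathwaySizeRange) == 2L,
            pathwaySizeRange[1] >= 1L,
            pathwaySizeRange[2] >= pathwaySizeRange[1],
            pathwaySizeRange[2] <= nProteins,
            nDrugs >= 1L, targetsPerDrug >= 1L,
            plantedFraction >= 0, plantedFraction <= 1,
            nPlantedDrugs >= 0L, nPlantedDrugs <= nDrugs,
            expressedFraction >= 0, expressedFraction <= 1,
            sourceRedundancy >= 0, sourceRedundancy <= 1)
  need <- ceiling(plantedFraction * targetsPerDrug)
  if (nPlantedDrugs > 0L && plantedFraction > 0 &&
      pathwaySizeRange[2] < need)
    stop(sprintf(paste0("configuration error: planted draw needs pathways ",
                        "of size >= %d but max pathway size is %d"),
                 need, pathwaySizeRange[2]), call. = FALSE)
  structure(list(seed = as.integer(seed), nProteins = as.integer(nProteins),
                 nPathways = as.integer(nPathways),
                 pathwaySizeRange = as.integer(pathwaySizeRange),
                 nDrugs = as.integer(nDrugs),
                 targetsPerDrug = as.integer(targetsPerDrug),
                 plantedFraction = plantedFraction,
                 nPlantedDrugs = as.integer(nPlantedDrugs),
                 tissues = tissues,
                 expressedFraction = expressedFraction,
                 sourceRedundancy = sourceRedundancy,
                 pchemblQualifying = pchemblQualifying,
                 pchemblNonQualifying = pchemblNonQualifying),
            class = "SimulationConfig")
}

.withSubstream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.labelSeed(seed, label))
  force(expr)
}

#' Generate the synthetic snapshot universe
#'
#' Builds, in memory, every file the pipeline consumes: the five source
#' snapshots (with sub-threshold, non-mammalian, non-protein, unreviewed and
#' unmappable noise rows so each adapter filter is exercised), the
#' cross-reference, the per-tissue expression table, the pathway GMT with
#' flags, the 3-level hierarchy, and a ground-truth manifest of planted
#' (drug, pathway) pairs and true drug-target pairs. Optionally writes the
#' whole tree to `dir` via [writeUniverse()].
#'
#' @param cfg a [simulationConfig()].
#' @param dir optional output directory; created if missing.
#' @return a `SyntheticUniverse` list: `cfg`, `snapshots` (named list of
#'   data.frames), `crossref`, `expression`, `pathways`
#'   (\linkS4class{PathwaySet}), `hierarchy`
#'   (\linkS4class{PathwayHierarchy}), `manifest`.
#' @export
generateUniverse <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  seed <- cfg$seed

  accs <- sprintf("P%05d", 10000L + seq_len(cfg$nProteins))
  genes <- sprintf("GEN%04d", seq_len(cfg$nProteins))
  acc2gene <- stats::setNames(genes, accs)
  gene2acc <- stats::setNames(accs, genes)

  ## ---- pathways and hierarchy ----
  nLeaf <- cfg$nPathways
  nRoot <- max(1L, ceiling(nLeaf / 20))
  nMid <- min(nLeaf, max(nRoot, ceiling(nLeaf / 5)))
  leafIds <- sprintf("R-HSA-%d", 100000L + seq_len(nLeaf))
  midIds <- sprintf("R-HSA-%d", 200000L + seq_len(nMid))
  rootIds <- sprintf("R-HSA-%d", 300000L + seq_len(nRoot))

  pw <- .withSubstream(seed, "pathways", {
    sizes <- sample(seq(cfg$pathwaySizeRange[1], cfg$pathwaySizeRange[2]),
                    nLeaf, replace = TRUE)
    members <- lapply(sizes, function(s) sort(sample(accs, s)))
    nDisease <- floor(0.05 * nLeaf)
    disease <- rep(FALSE, nLeaf)
    if (nDisease > 0L) disease[sample.int(nLeaf, nDisease)] <- TRUE
    list(members = members, disease = disease)
  })

  leafMid <- rep_len(midIds, nLeaf)      # leaf i hangs under leafMid[i]
  midRoot <- rep_len(rootIds, nMid)
  hierarchy <- new("PathwayHierarchy",
                   parent = c(midRoot, leafMid),
                   child = c(midIds, leafIds))

  midMembers <- lapply(midIds, function(m)
    sort(unique(unlist(pw$members[leafMid == m]))))
  rootMembers <- lapply(rootIds, function(r)
    sort(unique(unlist(midMembers[midRoot == r]))))

  pathways <- new("PathwaySet",
    stId = c(leafIds, midIds, rootIds),
    name = c(sprintf("Leaf pathway %d", seq_len(nLeaf)),
             sprintf("Mid-level pathway %d", seq_len(nMid)),
             sprintf("Top-level category %d", seq_len(nRoot))),
    members = stats::setNames(c(pw$members, midMembers, rootMembers),
                              c(leafIds, midIds, rootIds)),
    isDisease = c(pw$disease, rep(FALSE, nMid + nRoot)),
    taxId = rep(9606L, nLeaf + nMid + nRoot))

  ## ---- drugs and true target pairs ----
  drugIdsV <- sprintf("CHEMBL%d", 2000000L + seq_len(cfg$nDrugs))
  need <- ceiling(cfg$plantedFraction * cfg$targetsPerDrug)
  planted <- data.frame(drug_id = character(), st_id = character(),
                        stringsAsFactors = FALSE)
  drugInfo <- .withSubstream(seed, "drugs", {
    targets <- vector("list", cfg$nDrugs)
    plantedPw <- character(0)
    if (cfg$nPlantedDrugs > 0L && need > 0L) {
      eligible <- which(!pw$disease & lengths(pw$members) >= need)
      if (length(eligible) == 0L)
        stop(paste("configuration error: no non-disease leaf pathway large",
                   "enough for the planted draw"), call. = FALSE)
      plantedPw <- leafIds[sample(eligible, cfg$nPlantedDrugs,
                                  replace = TRUE)]
    }
    for (i in seq_len(cfg$nDrugs)) {
      if (i <= length(plantedPw)) {
        inPw <- sample(pw$members[[match(plantedPw[i], leafIds)]], need)
        rest <- sample(setdiff(accs, inPw), cfg$targetsPerDrug - need)
        targets[[i]] <- c(inPw, rest)
      } else {
        targets[[i]] <- sample(accs, cfg$targetsPerDrug)
      }
    }
    list(targets = targets, plantedPw = plantedPw)
  })
  if (length(drugInfo$plantedPw) > 0L)
    planted <- data.frame(drug_id = drugIdsV[seq_along(drugInfo$plantedPw)],
                          st_id = drugInfo$plantedPw,
                          stringsAsFactors = FALSE)
  pairs <- data.frame(
    drug_id = rep(drugIdsV, lengths(drugInfo$targets)),
    accession = unlist(drugInfo$targets, use.names = FALSE),
    stringsAsFactors = FALSE)

  ## ---- assign each true pair to one or two sources ----
  pairs <- .withSubstream(seed, "assignment", {
    primary <- sample(.SOURCES, nrow(pairs), replace = TRUE)
    second <- rep(NA_character_, nrow(pairs))
    dup <- stats::runif(nrow(pairs)) < cfg$sourceRedundancy
    for (i in which(dup))
      second[i] <- sample(setdiff(.SOURCES, primary[i]), 1L)
    pairs$primary <- primary
    pairs$second <- second
    pairs
  })
  inSource <- function(src) pairs$primary == src |
    (!is.na(pairs$second) & pairs$second == src)

  drugIdx <- stats::setNames(seq_along(drugIdsV), drugIdsV)
  accIdx <- stats::setNames(seq_along(accs), accs)
  decoys <- sprintf("Q%05d", 90000L + 1:5)

  ## ---- ChEMBL snapshot ----
  chembl <- .withSubstream(seed, "chembl", {
    sel <- pairs[inSource("chembl"), c("drug_id", "accession")]
    rows <- list()
    qf <- function(nn) sprintf("%.2f", pmax(5,
      stats::rnorm(nn, cfg$pchemblQualifying[["mean"]],
                   cfg$pchemblQualifying[["sd"]])))
    nq <- function(nn) sprintf("%.2f", pmin(4.99, pmax(0,
      stats::rnorm(nn, cfg$pchemblNonQualifying[["mean"]],
                   cfg$pchemblNonQualifying[["sd"]]))))
    if (nrow(sel) > 0L) {
      kind <- sample(c("plain", "moa", "rat"), nrow(sel), replace = TRUE,
                     prob = c(0.75, 0.1, 0.15))
      for (i in seq_len(nrow(sel))) {
        a <- sel$accession[i]; d <- sel$drug_id[i]
        if (kind[i] == "moa") {
          rows[[length(rows) + 1L]] <- data.frame(
            drug_id = d, target_id = a, pchembl = "",
            organism_class = "human", target_type = "single_protein",
            family_members = "", gene_symbol = acc2gene[[a]],
            evidence = "mechanism_of_action", stringsAsFactors = FALSE)
        } else if (kind[i] == "rat") {
          rows[[length(rows) + 1L]] <- data.frame(
            drug_id = d, target_id = paste0("RAT-", acc2gene[[a]]),
            pchembl = qf(1), organism_class = "mammal_nonhuman",
            target_type = "single_protein", family_members = "",
            gene_symbol = acc2gene[[a]], evidence = "assay",
            stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            drug_id = d, target_id = a, pchembl = qf(1),
            organism_class = "human", target_type = "single_protein",
            family_members = "", gene_symbol = acc2gene[[a]],
            evidence = "assay", stringsAsFactors = FALSE)
        }
      }
      ## merge some per-drug pairs of plain rows into protein-family rows
      df <- do.call(rbind, rows)
      plain <- which(df$target_type == "single_protein" &
                     df$organism_class == "human" & df$evidence == "assay")
      byDrug <- split(plain, df$drug_id[plain])
      famN <- 0L
      drop <- integer(0)
      for (idx in byDrug) {
        if (length(idx) >= 2L && stats::runif(1) < 0.3) {
          famN <- famN + 1L
          accPair <- df$target_id[idx[1:2]]
          df$family_members[idx[1]] <- paste(sort(accPair), collapse = ";")
          df$target_id[idx[1]] <- sprintf("FAMILY-%04d", famN)
          df$target_type[idx[1]] <- "protein_family"
          drop <- c(drop, idx[2])
        }
      }
      if (length(drop) > 0L) df <- df[-drop, , drop = FALSE]
      rows <- list(df)
    }
    df <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
    df
  })

  ## ---- assemble remaining snapshots ----
  mkdf <- function(...) data.frame(..., stringsAsFactors = FALSE)

  dbSel <- pairs[inSource("drugbank"), c("drug_id", "accession")]
  drugbank <- mkdf(drugbank_id = sprintf("DB%05d", drugIdx[dbSel$drug_id]),
                   accession = dbSel$accession)
  drugbank <- rbind(drugbank,
                    mkdf(drugbank_id = "DB99999", accession = accs[1]))

  ttdSel <- pairs[inSource("ttd"), c("drug_id", "accession")]
  ttd <- mkdf(ttd_id = sprintf("D0%04d", drugIdx[ttdSel$drug_id]),
              pubchem_cid = as.character(5000000L + drugIdx[ttdSel$drug_id]),
              uniprot_name = paste0(acc2gene[ttdSel$accession], "_HUMAN"))
  ttd <- rbind(ttd,
               mkdf(ttd_id = "D09998", pubchem_cid = "9999999",
                    uniprot_name = paste0(genes[1], "_HUMAN")),
               mkdf(ttd_id = "D09999",
                    pubchem_cid = as.character(5000001L),
                    uniprot_name = "GHOST_HUMAN"))

  pgSel <- pairs[inSource("pharmgkb"), c("drug_id", "accession")]
  pharmgkb <- mkdf(pharmgkb_id = sprintf("PA%05d", drugIdx[pgSel$drug_id]),
                   gene_symbol = unname(acc2gene[pgSel$accession]))
  pharmgkb <- rbind(pharmgkb,
                    mkdf(pharmgkb_id = "PA99999", gene_symbol = genes[1]),
                    mkdf(pharmgkb_id = sprintf("PA%05d", 1L),
                         gene_symbol = "GHOSTGENE"))

  iuSel <- pairs[inSource("iuphar"), c("drug_id", "accession")]
  iuphar <- mkdf(ligand_id = as.character(4000L + drugIdx[iuSel$drug_id]),
                 target_id = as.character(7000L + accIdx[iuSel$accession]))
  iuphar <- rbind(iuphar,
                  mkdf(ligand_id = as.character(4001L),
                       target_id = "9999"),
                  if (nrow(iuSel) > 0L) iuphar[1, ] else NULL)

  ## ChEMBL noise rows exercising every filter
  chemblNoise <- .withSubstream(seed, "chembl-noise", {
    nn <- max(3L, ceiling(0.1 * nrow(pairs)))
    noise <- mkdf(
      drug_id = sample(drugIdsV, nn, replace = TRUE),
      target_id = sample(accs, nn, replace = TRUE),
      pchembl = sprintf("%.2f", pmin(4.99, pmax(0,
        stats::rnorm(nn, cfg$pchemblNonQualifying[["mean"]],
                     cfg$pchemblNonQualifying[["sd"]])))),
      organism_class = "human", target_type = "single_protein",
      family_members = "", gene_symbol = "", evidence = "assay")
    noise$gene_symbol <- unname(acc2gene[noise$target_id])
    extra <- mkdf(
      drug_id = drugIdsV[c(1, 1, 1)],
      target_id = c("ZEBRAFISH-1", "CHEBI:1234", decoys[1]),
      pchembl = c("7.00", "7.00", "7.00"),
      organism_class = c("nonmammal", "human", "human"),
      target_type = c("single_protein", "non_protein", "single_protein"),
      family_members = "",
      gene_symbol = c(genes[1], "", "DECOYGENE"),
      evidence = "assay")
    rbind(noise, extra)
  })
  chembl <- rbind(chembl, chemblNoise)
  rownames(chembl) <- NULL

  ## ---- crossref ----
  xr <- rbind(
    mkdf(namespace_a = "uniprot_acc", id_a = accs,
         namespace_b = "gene_symbol", id_b = genes),
    mkdf(namespace_a = "uniprot_name", id_a = paste0(genes, "_HUMAN"),
         namespace_b = "uniprot_acc", id_b = accs),
    mkdf(namespace_a = "drugbank", id_a = sprintf("DB%05d",
                                                  seq_len(cfg$nDrugs)),
         namespace_b = "chembl", id_b = drugIdsV),
    mkdf(namespace_a = "pubchem",
         id_a = as.character(5000000L + seq_len(cfg$nDrugs)),
         namespace_b = "chembl", id_b = drugIdsV),
    mkdf(namespace_a = "pharmgkb", id_a = sprintf("PA%05d",
                                                  seq_len(cfg$nDrugs)),
         namespace_b = "chembl", id_b = drugIdsV),
    mkdf(namespace_a = "iuphar_ligand",
         id_a = as.character(4000L + seq_len(cfg$nDrugs)),
         namespace_b = "chembl", id_b = drugIdsV),
    mkdf(namespace_a = "iuphar_target",
         id_a = as.character(7000L + seq_len(cfg$nProteins)),
         namespace_b = "uniprot_acc", id_b = accs),
    mkdf(namespace_a = "chebi",
         id_a = sprintf("CHEBI:%d", 10000L + seq_len(cfg$nDrugs)),
         namespace_b = "chembl", id_b = drugIdsV))
  rownames(xr) <- NULL

  ## ---- expression ----
  expression <- .withSubstream(seed, "expression", {
    out <- list()
    exprGenes <- list()
    for (tis in cfg$tissues) {
      shuffled <- sample(genes)
      nMissing <- floor(0.05 * length(genes))
      measured <- shuffled[seq_len(length(genes) - nMissing)]
      nExpr <- round(cfg$expressedFraction * length(genes))
      nExpr <- min(nExpr, length(measured))
      expr <- measured[seq_len(nExpr)]
      low <- setdiff(measured, expr)
      vals <- c(stats::rlnorm(length(expr), meanlog = log(20), sdlog = 1),
                stats::runif(length(low), 0, 0.9))
      df <- mkdf(gene_symbol = c(expr, low), tissue = tis,
                 ntpm = sprintf("%.3f", vals))
      out[[tis]] <- df[order(df$gene_symbol, method = "radix"), ,
                       drop = FALSE]
      exprGenes[[tis]] <- sort(expr)
    }
    list(table = do.call(rbind, out), genes = exprGenes)
  })
  exprTab <- expression$table
  rownames(exprTab) <- NULL

  manifest <- list(
    seed = seed,
    planted = planted,
    pairs = pairs[order(pairs$drug_id, pairs$accession, method = "radix"),
                  c("drug_id", "accession")],
    expressed_genes = expression$genes)
  rownames(manifest$pairs) <- NULL

  universe <- structure(list(
    cfg = cfg,
    snapshots = list(chembl = chembl, drugbank = drugbank, ttd = ttd,
                     pharmgkb = pharmgkb, iuphar = iuphar),
    crossref = xr,
    expression = exprTab,
    pathways = pathways,
    hierarchy = hierarchy,
    manifest = manifest), class = "SyntheticUniverse")
  if (!is.null(dir)) writeUniverse(universe, dir)
  universe
}

#' Generate a null universe (no planted signal)
#'
#' Same file set as [generateUniverse()] with the planted fraction forced
#' to zero: every drug draws its targets uniformly from the proteome, so
#' any significant pathway is a false discovery. Used for empirical FDR
#' calibration.
#'
#' @inheritParams generateUniverse
#' @return a `SyntheticUniverse`.
#' @export
generateNull <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  cfg$plantedFraction <- 0
  cfg$nPlantedDrugs <- 0L
  generateUniverse(cfg, dir)
}

#' Write a synthetic universe as a snapshot directory
#'
#' Files: `chembl.tsv`, `drugbank.tsv`, `ttd.tsv`, `pharmgkb.tsv`,
#' `iuphar.tsv`, `crossref.tsv`, `expression.tsv`, `pathways.gmt`,
#' `pathway_flags.tsv`, `hierarchy.tsv`, `manifest.json`. Output is
#' byte-stable for a given configuration.
#'
#' @param universe a `SyntheticUniverse` from [generateUniverse()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeUniverse <- function(universe, dir) {
  stopifnot(inherits(universe, "SyntheticUniverse"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (src in names(universe$snapshots))
    .writeTsv(universe$snapshots[[src]],
              file.path(dir, paste0(src, ".tsv")))
  .writeTsv(universe$crossref, file.path(dir, "crossref.tsv"))
  .writeTsv(universe$expression, file.path(dir, "expression.tsv"))
  writePathwaySet(universe$pathways, file.path(dir, "pathways.gmt"),
                  file.path(dir, "pathway_flags.tsv"))
  writeHierarchy(universe$hierarchy, file.path(dir, "hierarchy.tsv"))
  jsonlite::write_json(universe$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Empirical false-discovery calibration under the global null
#'
#' Generates `nReps` null universes (in memory), builds profiles from each
#' replicate's true drug-target pairs, runs the overrepresentation test per
#' drug at the given FDR cutoff, and returns the mean false discovery
#' proportion. Under the global null every reported pathway is a false
#' discovery, so per drug FDP = 1 when anything is reported and 0
#' otherwise; Benjamini-Hochberg bounds the mean at the cutoff.
#'
#' @param nReps number of null replicates.
#' @param cfg a [simulationConfig()]; its seed is re-derived per replicate.
#' @param seed master seed for the replicate series.
#' @param fdrCutoff FDR cutoff (default 0.05).
#' @return list with `meanFdp`, `nDrugs` (total drug-level tests), `nReps`.
#' @export
empiricalNullFdr <- function(nReps, cfg, seed, fdrCutoff = 0.05) {
  stopifnot(inherits(cfg, "SimulationConfig"), nReps >= 1L)
  fdp <- numeric(0)
  for (r in seq_len(nReps)) {
    cfg$seed <- .labelSeed(seed, paste0("null-rep-", r))
    u <- generateNull(cfg)
    pairs <- u$manifest$pairs
    recs <- .makeRecords(pairs$drug_id, pairs$accession, "chembl", "assay")
    profiles <- buildProfiles(recs)
    for (d in drugIds(profiles)) {
      res <- runOra(profileAccessions(profiles, d), u$pathways,
                    u$hierarchy, fdrCutoff = fdrCutoff, drug = d)
      fdp <- c(fdp, as.numeric(nrow(resultTable(res)) > 0L))
    }
  }
  list(meanFdp = mean(fdp), nDrugs = length(fdp), nReps = nReps)
}
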