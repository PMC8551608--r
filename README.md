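# drugpath

Tissue-specific drug target profiles and pathway overrepresentation, fully
offline.

## What it does, and for whom

Drugs rarely cause organ toxicity through a single protein. A practical
systems-level handle is the set of biological pathways a compound can
perturb: collect every protein a drug is evidenced to modulate across the
major target databases, keep the ones expressed in the tissue of interest,
and test which pathways contain more of them than chance would allow.
drugpath implements this pipeline for computational toxicologists and
cheminformaticians who want it reproducible and testable against local
*snapshot files* rather than live web services:

1. **Source adapters** — parse ChEMBL-, DrugBank-, TTD-, PharmGKB- and
   IUPHAR-style tables into common drug–protein records, applying each
   source's conventions: the inclusive pChEMBL ≥ 5 bioactivity filter,
   mechanism-of-action targets, protein-family expansion, ortholog lifting
   of mammalian targets via shared gene symbols, PubChem bridging,
   UniProt-name translation, and a reviewed-human-only restriction.
2. **Harmonization** — one deduplicated protein pool per drug, with
   per-source provenance.
3. **Tissue filter** (optional) — drop proteins whose genes fall below a
   consensus expression cutoff (default 1 nTPM) in a chosen tissue.
4. **Enrichment** — for each pathway, the hypergeometric upper tail

   *p* = P(X ≥ k),  X ~ Hypergeometric(N, K, n),

   with k the profile/pathway overlap, K the pathway size in the universe,
   n the submitted proteins found in the universe, N the universe size
   (union of all annotated proteins by default). Benjamini–Hochberg
   correction runs over the pathways with k ≥ 1; pathways pass at
   FDR ≤ 0.05, after excluding disease-flagged pathways and pruning
   top-level hierarchy terms.
5. **Group comparison** — affected-compound fractions per pathway,
   "at least 10% / 20% of the group" threshold sets with intersections and
   exclusives, bipartite drug–pathway edge lists, and recovery/novelty
   scoring against a reference edge list.

A seeded synthetic-snapshot generator (`generateUniverse()`) emulates the
whole file ecosystem with planted drug→pathway enrichment, so the entire
pipeline is testable — and calibratable — with no downloads.

## Worked example

The package ships a hand-built micro snapshot directory (2 drugs,
8 proteins, 3 leaf pathways under 1 root, 2 tissues):

```r
library(drugpath)
micro <- system.file("extdata", "micro", package = "drugpath")
run <- runPipeline(file.path(micro, "drugs.txt"), micro,
                   tissue = "heart", outDir = tempfile())
run$report
#>    drug_id raw_targets after_dedup after_tissue_filter found_in_universe
#> 1 CHEMBL10           6           4                   3                 3
#> 2 CHEMBL20           3           3                   2                 2
#>   significant_pathways status
#> 1                    1     ok
#> 2                    0     ok
```

CHEMBL10 contributes six raw records (a boundary pChEMBL = 5.00 assay, a
two-member protein family, an ortholog-lifted rat assay, plus DrugBank and
TTD rows); deduplication leaves 4 proteins, the heart filter removes one
gene at 0.2 nTPM, and the three survivors exactly fill one 3-protein
pathway in the 8-protein universe:

```r
resultTable(run$results$CHEMBL10)
#>           stId                                 name k K n N     pValue
#> 1 R-HSA-100001 Cardiac repolarisation micro pathway 3 3 3 8 0.01785714
#>          fdr
#> 1 0.03571429
```

The p-value is 1/56 — one favourable draw among C(8,3) — and the BH
adjustment over the two tested pathways doubles it to 1/28 ≈ 0.036, under
the 0.05 cutoff. The flat CSV written to `outDir` carries the schema
`molecule_chembl_id,Names,stIds,fdrs,pValues`. CHEMBL20's best pathway
(fdr 9/28) misses the cutoff, so it reports zero significant pathways.

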