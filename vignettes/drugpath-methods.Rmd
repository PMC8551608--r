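---
title: "Connecting drugs to tissue-specific pathways: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connecting drugs to tissue-specific pathways: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Organ-level drug toxicity (cardiotoxicity, hepatotoxicity) is rarely
explained by a single target. A useful systems-level proxy is the set of
biological pathways a compound can perturb: the proteins a drug is
evidenced to modulate, pooled across target databases, restricted to the
tissue of interest, and tested for overrepresentation against a curated
pathway collection. drugpath implements that pipeline offline, against
local snapshot files, so every stage is deterministic and testable.

The pipeline has four stages plus a comparison layer:

1. **Source adapters** parse five per-source snapshot tables (ChEMBL-,
   DrugBank-, TTD-, PharmGKB- and IUPHAR-style) into a common
   drug-protein record format, applying each source's filters and
   identifier translations.
2. **Harmonization** unions the records per drug and removes duplicate
   drug-protein pairs, keeping per-source provenance.
3. **Tissue filtering** (optional) drops proteins whose genes show low or
   no consensus mRNA expression in a chosen tissue.
4. **Enrichment** connects the surviving protein pool to pathways by a
   hypergeometric overrepresentation test with Benjamini-Hochberg FDR
   control, disease-pathway exclusion and hierarchy pruning.
5. **Group comparison** contrasts pathway profiles of drug groups
   (e.g. cardiotoxic vs. therapeutic) by affected-compound frequency and
   scores discovered links against a reference edge list.

## Adapter rules

Each source contributes evidence under its own conventions:

* **ChEMBL-style activities.** An assay row qualifies when its pChEMBL
  (the negative log10 of a molar IC50/XC50/EC50/AC50/Ki/Kd/Potency) is at
  least `pchemblMin` (default 5, i.e. 10 uM activity; the threshold is
  inclusive). Mechanism-of-action rows qualify without a pChEMBL. A
  drug-target pair qualifies when *any* of its rows qualifies; no
  aggregation across conflicting rows is attempted. Protein-family
  targets expand to all member accessions. Non-protein and non-mammalian
  targets are dropped. Mammalian non-human targets are lifted to the
  human protein sharing the gene symbol (`includeOrthologLift`, default
  on, because cross-species concordance is imperfect and a user may want
  the conservative run).
* **DrugBank-style tables** are keyed by DrugBank IDs and translated to
  ChEMBL IDs through the cross-reference; a compound mapping to several
  ChEMBL IDs fans out to all of them, with a warning, never a silent
  pick.
* **TTD-style tables** carry no ChEMBL IDs and no accessions: compounds
  are bridged through PubChem CIDs, and UniProt entry *names* are
  translated to accessions.
* **PharmGKB-style tables** relate drugs to target genes; each gene
  resolves to every reviewed human accession it expresses.
* **IUPHAR-style tables** use one target identifier across organisms; it
  is resolved to the human accession only.

**Reviewed-human registry.** Every adapter must certify that an emitted
accession is a reviewed (manually curated) human UniProt entry. In this
package the accession-to-gene-symbol block of the cross-reference file
plays that role: it enumerates exactly the reviewed human entries, like a
SwissProt slice, and membership is the check. This keeps one mechanism
across all five adapters and makes the registry an explicit, versionable
input.

Rows that fail a filter are never fatal: they accumulate in a per-source
rejects report (reason-coded: `below-threshold`, `unreviewed-accession`,
`unmapped-drug`, `no-human-equivalent`, ...) so a single malformed row
cannot kill a batch run, and the run report still accounts for it.

## The enrichment model

For a drug whose filtered profile contains $n$ proteins found in the
annotation universe of size $N$, and a pathway with $K$ universe proteins
of which $k$ are in the profile, the overrepresentation p-value is the
hypergeometric upper tail

$$ p = P(X \ge k), \qquad X \sim \mathrm{Hypergeometric}(N, K, n), $$

i.e. the chance of drawing at least $k$ pathway members in $n$ draws
without replacement. The tail is accumulated from log-binomial
coefficients (`lchoose`), which keeps it exact to ~1e-12 relative error
for universes up to at least $10^4$ proteins; tests verify it against
exhaustive enumeration of all draws on small instances and against the
survival function.

Multiplicity is controlled by the Benjamini-Hochberg step-up rule,
$\mathrm{adj}_{(i)} = \min_{j \ge i} p_{(j)} \, m / j$, clipped at 1.
Two choices deserve emphasis because reported FDR values cannot be
reproduced without them:

* **The universe** defaults to the union of all annotated member
  accessions (after disease exclusion). An explicit universe can be
  supplied instead. Submitted proteins outside the universe are counted
  as "not found" and excluded from the test.
* **The BH family size** $m$ is the number of pathways with overlap
  $k \ge 1$, mirroring analysis services that only report hit pathways.
  A pathway with zero overlap is not tested and can never change a
  reported value (asserted by test).

Reported pathways are those with FDR at or below `fdrCutoff` (default
0.05). Disease-flagged pathways are excluded by default from both the
universe and the candidates. Results sort by (fdr, p, stId); the stable-ID
tie-break makes output byte-stable.

**Hierarchy pruning.** Pathway collections are organized hierarchically,
and top-level terms ("Cell Cycle"-like collective categories) are too
generic to interpret. Depth is the shortest path from any root of the
parent-child graph; results with depth below `minDepth` (default 1, i.e.
roots only are dropped) are pruned. The exact level at which "lower-level"
begins is a genuinely open choice, which is why it is a flag rather than a
constant. Pathways absent from the hierarchy file are retained with a
warning: a data gap should not silently delete results.

## Tissue filtering

Consensus mRNA abundance (nTPM) is used rather than protein-level
evidence, because protein data is missing for relevant genes (ion
channels among them). "Low or no expression" is quantified as
nTPM < `minNtpm` with a default of 1.0, the conventional
"not detected below 1 nTPM" rule for consensus expression data; no
authoritative numeric cutoff exists, so it is configurable and the
threshold is inclusive (a gene at exactly 1.0 survives). Accessions with
no expression row (or no gene mapping) are dropped by default — absence
of evidence is treated conservatively — but counted in the run report,
and `keepUnmeasured = TRUE` retains them. An accession mapping to several
gene symbols is kept if *any* mapped gene passes.

## Group comparison

For a drug group, a pathway's affected-compound fraction is
`n_hit / n_group`. The denominator is the number of drugs in the group
with at least one significant pathway: group sizes naturally shrink along
the pipeline (drugs lose all targets to the tissue filter, or all
pathways to the FDR cutoff), and using the post-enrichment denominator
makes the fractions comparable across groups; drugs with empty sets are
still recorded in the output metadata. Frequency thresholds ("at least
10%", "at least 20%") are inclusive, and threshold sets are antitone in
the fraction by construction. `noveltyVsReference()` partitions each
drug's discovered pathway set against a reference compound-pathway edge
list into recovered / novel / missed, with the conservation identities
asserted in tests.

## The synthetic universe

`generateUniverse()` emulates the full snapshot ecosystem: five source
tables, the cross-reference, per-tissue expression, a pathway GMT with a
disease-flag sidecar, a three-level hierarchy (roots, mid-level terms,
leaves; mid and root members are the unions of their descendants), and a
ground-truth manifest. Defaults — 1000 proteins, 100 leaf pathways of
size 5-50, 50 drugs with 10 targets each, 20 planted drugs drawing 80% of
their targets from one assigned leaf pathway — are chosen as a desk-scale
caricature of the real setting: cohorts of tens of compounds, profiles of
~10 proteins, pathways of tens of members. At these sizes the planted
signal is overwhelmingly recoverable (the hypergeometric tail at
$k \approx 8$, $K \le 50$, $n = 10$, $N \approx 1000$ is ~1e-9), which is
the point: recovery failures indicate plumbing bugs, not statistical bad
luck.

Realism choices: qualifying assay pChEMBL values are normal around 7
(clamped at the threshold 5), sub-threshold noise rows normal around 4.2;
half of the true pairs are deposited in a second source
(`sourceRedundancy = 0.5`) to exercise cross-source deduplication; 5% of
leaf pathways are disease-flagged; per tissue, 60% of genes are expressed
with lognormal nTPM (median 20), the rest sit uniformly below 0.9 —
cleanly separated around the default 1.0 cutoff — and 5% of genes have no
row at all, exercising the unmeasured path. Every file also receives
noise rows (below-threshold, non-mammalian, non-protein, unreviewed,
unmappable) so each adapter filter fires on every generated corpus.

Each output file draws from its own RNG substream derived from the master
seed by a label hash, so the same seed yields byte-identical trees and
adding a new output file never perturbs existing ones.

What the generator does **not** emulate: real chemistry (no structures),
realistic pathway topology beyond a three-level tree, correlated
annotation errors between databases, and realistic expression covariance
across tissues. Passing the planted-recovery and calibration tests
therefore demonstrates the statistical machinery and the plumbing are
correct — not that any particular biological conclusion from real
snapshots is right, which always depends on the database versions used.

## Calibration

Under a global null (all drugs draw targets uniformly), every reported
pathway is a false discovery, so the per-drug false discovery proportion
is 1 when anything is reported and 0 otherwise, and Benjamini-Hochberg
bounds its mean by the cutoff. The package's calibration harness
(`empiricalNullFdr()`) runs 1000 null replicates of a compact
configuration (300 proteins, 40 leaf pathways, 4 drugs per replicate —
4000 drug-level tests, a Monte-Carlo design that keeps the standard error
of the mean FDP near 0.003) and checks the mean FDP at cutoff 0.05
against 0.07 (the BH guarantee plus Monte-Carlo slack). Because
hypergeometric p-values are discrete and conservative, observed values
sit well below the nominal level.

## Numerical and degenerate-input choices

* All thresholds are inclusive (pChEMBL >= 5, nTPM >= 1, fraction >= 10%,
  FDR <= cutoff).
* `hypergeomUpperTail(0, ...)` is exactly 1; preconditions
  ($k \le \min(n, K)$, $K \le N$, $n \le N$) are hard domain errors.
* An empty profile after filtering yields a `no-proteins-found` status,
  never an exception; a drug absent from all sources yields a report row.
* Output numbers are rendered with `%.10g`; every table has a total sort
  order; no timestamps enter data files — repeated runs are
  byte-identical.
* The hierarchy is validated acyclic on construction; depth queries on
  nodes outside the hierarchy return `NA` and prune keeps them with a
  warning.

## Worked example

```{r example}
library(drugpath)

micro <- system.file("extdata", "micro", package = "drugpath")
run <- runPipeline(file.path(micro, "drugs.txt"), micro,
                   tissue = "heart", outDir = tempfile())
run$report
resultTable(run$results$CHEMBL10)
```

## Known limitations

* The adapters consume documented snapshot schemas, not the live services
  or native dumps (DrugBank XML, TTD flat files); converting real dumps
  into the snapshot layout is the user's responsibility.
* Reviewed-entry status is delegated entirely to the cross-reference
  registry; there is no live UniProt verification.
* Enrichment is overrepresentation-only: no ranked (GSEA-style) or
  topology-aware testing, and no interactor augmentation.
* Group comparisons are descriptive frequencies; no between-group
  significance testing is attempted.
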