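Package: drugpath
Title: Tissue-Specific Drug Target Profiles and Pathway Overrepresentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds harmonized drug-target protein profiles from local
    snapshots of five target databases (ChEMBL-, DrugBank-, TTD-, PharmGKB-
    and IUPHAR-style tables), optionally restricts them to proteins expressed
    in a chosen tissue using consensus mRNA abundance (nTPM), and connects
    each drug to biological pathways with a hypergeometric overrepresentation
    test under Benjamini-Hochberg false-discovery-rate control, excluding
    disease pathways and pruning high-level pathway-hierarchy terms. Pathway
    profiles of drug groups (for example cardiotoxic versus hepatotoxic
    versus therapeutic compounds) are compared by affected-compound
    frequency, and discovered drug-pathway links can be scored against a
    reference edge list. A seeded synthetic-snapshot generator with planted
    drug-to-pathway enrichment makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
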