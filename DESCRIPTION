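Package: complexcat
Title: Compilation and Analysis of Protein Complex Catalogues
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds non-redundant catalogues of protein complexes from
    redundant multi-database collections by ranking complexes with a Gene
    Ontology (biological process) semantic-similarity significance score and
    merging or discarding overlapping complexes by their Jaccard coefficient.
    Provides downstream analyses of the resulting catalogue: derivation of
    co-complex protein pairs and their overlap with protein-protein
    interaction references, bipartite drug-complex networks with hub and
    target-usage statistics, a permutation test for enrichment of known
    drug-drug interactions among co-complex drug pairs, hypergeometric
    disease-complex association with Fisher meta-analysis of per-study
    disease-gene p-values, enumeration of drug-repositioning candidates from
    disease-specific complex-drug subnetworks, and match-based evaluation of
    predicted complex sets (precision/recall/F and Sn/PPV/Accuracy). A
    seeded synthetic-data generator produces complete input bundles with
    planted ground truth so every stage can be exercised without external
    databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
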