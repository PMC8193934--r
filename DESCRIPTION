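Package: netpharm
Title: Network Pharmacology Inference for Multi-Herb Formulas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the network-pharmacology inference chain used to
    dissect multi-herb decoctions: oral-bioavailability/drug-likeness
    ingredient screening, ingredient-to-target mapping, multi-source
    disease-gene aggregation with Venn partitioning,
    herb-ingredient-target network construction, confidence-filtered
    protein-protein interaction graphs, hub-gene extraction by iterative
    above-median filtering on six node centralities (betweenness,
    closeness, degree, eigenvector, local average connectivity, network
    centrality), hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, and threshold classification of
    differential-expression tables. A synthetic-data generator with a
    ground-truth ledger supports end-to-end testing without database
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
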