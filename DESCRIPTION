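Package: pathrank
Title: Pathway-Group Gene Selection and Classification via Active-Subnetwork Enrichment Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies two-class gene expression data by grouping genes into
    biologically coherent pathway groups and ranking those groups by their
    cross-validated predictive power. Significant genes seed a greedy active
    subnetwork search on a protein-protein interaction network; subnetworks are
    tested for pathway over-representation with hypergeometric tests and
    Benjamini-Hochberg adjustment, repeated over iterations; each surviving
    pathway's gene group is scored by Monte Carlo cross-validated random forest
    (or SVM) accuracy; classifiers built on the accumulated top-k groups are
    evaluated on held-out samples. Includes readers for expression/label TSV,
    GMT gene sets and PIN edge lists, a synthetic-data generator with planted
    differentially expressed pathways, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    randomForest,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
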