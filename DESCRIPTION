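Package: genenetbench
Title: Benchmarking Supervised Learning and Label Propagation for
    Network-Based Gene Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for guilt-by-association gene classification on weighted
    undirected molecular networks. Builds three network representations per
    gene (adjacency rows, random-walk-with-restart influence rows and node2vec
    embeddings), trains and evaluates label-propagation and L2-regularized
    logistic-regression classifiers on geneset collections under temporal,
    study-bias and stratified cross-validation schemes, and computes
    prior-normalized precision-recall metrics, competition rankings and paired
    significance tests with false-discovery-rate control. Includes a
    planted-partition simulator that generates networks, geneset collections,
    annotation dates and study-bias counts so the whole pipeline can be
    exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    yaml,
    optparse
Config/testthat/edition: 3
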