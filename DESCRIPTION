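Package: icellr
Title: Integrated Cell Networks by Simultaneous Symmetric Non-Negative
    Matrix Tri-Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses multiple condition-specific molecular interaction
    networks (protein-protein interaction, co-expression, genetic
    interaction) into one integrated network per condition by
    simultaneous symmetric non-negative matrix tri-factorization with a
    shared cluster-indicator factor, then quantifies per-gene topological
    rewiring between conditions with graphlet degree vector distances.
    Includes clustering-stability selection of the number of clusters,
    graphlet correlation distances (GCD-11) against seven random-graph
    null models, hypergeometric enrichment and depletion statistics for
    gene clusters and gene sets, and a synthetic-data generator with
    planted co-cluster and rewiring ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
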