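Package: mbfuse
Title: Fuzzy Rule Matrices, Collinearity Clustering and Literature
    Network Fusion for Microbiome Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of sparse, collinear microbiome abundance
    tables. Learns a Takagi-Sugeno fuzzy inference system from a
    label-augmented abundance matrix and renders it as an integer rule
    matrix that preserves the correlation structure while absorbing
    sparsity; removes collinearity by density-based (DBSCAN) clustering of
    features with an epsilon grid search driven by an aliased-coefficient
    stopping rule, collapsing each cluster onto its first principal-
    component loading; prioritizes taxa with adaptive-LASSO cluster scores
    distributed back to features; and fuses the data-driven clusters with a
    literature-derived taxon co-occurrence network carrying node sizes
    (study occurrence) and node scores (outcome association). Includes a
    synthetic-fixture generator emulating zero-inflated, block-collinear,
    label-associated abundance data so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    nnet,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
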