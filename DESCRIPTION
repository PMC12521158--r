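Package: fcresponse
Title: Graph-Theoretic Functional Connectome Analysis for Antidepressant
    Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for graph-theoretical analysis of resting-state
    functional brain networks in treatment-response studies. Builds
    Pearson functional connectivity matrices from regional BOLD time
    series, binarizes them across a sparsity sweep, computes global and
    nodal topological metrics (clustering, path length, efficiencies,
    small-world normalization against degree-preserving null networks,
    assortativity, modularity) with area-under-curve integration across
    thresholds, compares groups by nonparametric permutation tests with
    false-discovery-rate control, and relates network topology to
    clinical outcome via partial correlation, forward likelihood-ratio
    logistic regression and ROC analysis. Includes a synthetic cohort
    generator with a modular block-correlation model so the full
    pipeline can be exercised and validated without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
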