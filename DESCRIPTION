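Package: riskfill
Title: Gap-Filling Extinction-Risk Status and Spatial Conservation
    Prioritization for Marine Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to infer the Red List extinction-risk status of
    data-deficient and not-evaluated marine species and to propagate those
    inferences into conservation planning. Provides a seeded synthetic-world
    generator, quadrant-split convex-hull range construction on an equal-area
    grid, performance-gated iterative trait imputation, balanced down-sampled
    ensembles of random forests and neural networks with within-algorithm
    consensus, complementary and strict merging of the two algorithms' calls,
    the D statistic of phylogenetic signal for binary traits, gap analysis
    against protected areas with log-linear range-size targets, and a greedy
    cell-removal prioritization ranking with status-based species weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    Matrix,
    nnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
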