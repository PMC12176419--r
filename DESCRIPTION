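Package: mixsel
Title: Nonlinear Mixed Selectivity Analysis for Multivoxel Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting nonlinear mixed selectivity (multivariate
    interaction effects) between a stimulus variable and a context variable in
    block-wise multivoxel activity patterns. Implements pattern difference
    decoding, within- and cross-context linear classification with
    run-respecting cross-validation, cross-decoding generalization ratios,
    per-participant permutation tests, hierarchical Bayesian posterior odds on
    group decoding accuracy, and representational-geometry analyses (condition
    dissimilarity matrices, multidimensional scaling, and reliability-corrected
    between-context geometry comparison). A seeded synthetic pattern generator
    with known additive, rotational, and reshaping tuning structure provides
    ground truth for every analysis stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    coda,
    optparse,
    rjags,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
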