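Package: phenostab
Title: Developmental Stability, Canalization and Phenotypic Plasticity from
    Leaf Asymmetry and Trait Variation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying developmental stability, canalization and
    phenotypic plasticity in designed plant experiments. Computes leaf
    fluctuating-asymmetry indices (FA1, FA2 and the variance-component index
    FA10 with measurement error partitioned out via a sides-by-units factorial
    ANOVA), diagnostic tests for directional asymmetry and antisymmetry,
    intra- and inter-individual coefficients of variation with CV-equality
    tests, ANCOVA-adjusted treatment means and plasticity indices, and the
    correlation machinery (Pearson and partial Pearson coefficients, slope
    difference tests, LSD comparisons) used to relate them. Includes a
    synthetic-data generator that emulates a two-round split-plot water
    treatment experiment so every stage of the pipeline can be validated
    against known generative parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
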