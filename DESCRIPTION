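Package: connpred
Title: Connectome-Based Prediction of Life Satisfaction from Resting-State
    Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for predicting a continuous psychological
    trait (life satisfaction) from resting-state functional connectomes.
    Covers post-processing of ROI time series (nuisance regression,
    band-pass filtering, framewise-displacement scrubbing), construction of
    vectorized Fisher-z connectivity feature matrices, dimensionality
    reduction by principal components followed by ridge regression with
    nested 10-fold cross-validation, permutation-based significance for
    predictive correlations, external-cohort validation by fold-model
    averaging, back-projection of model weights to edge space with per-edge
    one-sample t-tests, and hypergeometric enrichment of contributing edges
    over nine resting-state networks. Includes a synthetic cohort generator
    with planted trait-coupled edges and motion artifacts so the whole
    pipeline is testable without access to any neuroimaging repository.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
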