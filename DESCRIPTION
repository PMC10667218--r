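Package: metalrisk
Title: Heavy-Metal Pollution Indexing, Health-Risk Assessment and
    Predictive Modelling for Surface Waters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing heavy-metal contamination of surface
    water bodies from tabular monitoring records: a weighted heavy-metal
    pollution index (HPI) with five-band drinking-water classification,
    a deterministic ingestion exposure model (average daily intake,
    hazard quotient/index, carcinogenic risk/index), a three-algorithm
    regression comparison harness (random forest, epsilon-insensitive
    RBF support vector regression, single-hidden-layer neural network)
    scored by MAE, RMSE, MAPE and R-squared under hold-out and k-fold
    validation, inverse-distance-weighted interpolation of station
    values to continuous surfaces, seasonal Pearson correlation
    summaries, and a Gaussian-copula synthetic sample generator with
    detection-limit censoring that emulates a multi-river two-season
    sampling design. All user-facing functions take a data frame of
    sample records first and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    purrr,
    randomForest,
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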