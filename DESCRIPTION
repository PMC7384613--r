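Package: movestates
Title: State-Switching Models for Predicting and Simulating Animal Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-step framework for modelling high-resolution animal
    movement: a behavioural-state classifier coupled with per-state
    stochastic velocity models, specified at the individual or colony
    level. Includes a parametric comparator based on a stochastic
    differential equation with spatially varying motility and potential
    surfaces, long-range stochastic trajectory simulation with nest
    geometry handling, evaluation metrics (one-step mean squared
    prediction error, simulation metric suites, moving-window reference
    bands), migratory-state segmentation for annual seabird tracks, and
    seeded synthetic-data generators for ant colonies and gull years.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
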