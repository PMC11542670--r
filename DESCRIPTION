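Package: gazeimpress
Title: Personality Traits, Gaze over Facial Areas, and Impression Ratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing and hierarchical Bayesian modelling of
    how observers' Big Five personality traits shape their eye movements over
    facial areas of interest (eyes, nose, mouth), and how gaze and traits
    together shape 7-point facial impression ratings. Raw gaze streams are
    turned into per-area gaze weights (Gaussian kernel density, area masks,
    per-pixel normalization, sampling-rate exclusion); gaze weights are
    modelled with a zero-inflated beta mixed regression and ratings with a
    hierarchical ordered-logistic regression, estimated jointly by
    Hamiltonian Monte Carlo with analytic gradients. Includes posterior
    summaries (split R-hat, highest density intervals, significance tables,
    random-effect significance proportions), between-condition contrast
    models for gaze-manipulation designs, predictive trait-response curves,
    and a synthetic-study generator with known ground truth for parameter
    recovery and null-calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    rjags,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
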