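Package: gagrowth
Title: Hierarchical Growth Modelling and Probabilistic Forecasting of
    Geographic Atrophy Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the enlargement of geographic atrophy
    lesions from longitudinal fundus-autofluorescence lesion-area series.
    Fits hierarchical Bayesian Gompertz, logistic, linear, effective-radius
    (square-root), von Bertalanffy and Mitscherlich growth curves with
    patient- and eye-level random effects; produces rolling one-step-ahead
    probabilistic forecasts scored by the continuous ranked probability
    score, absolute error of the predictive median and prediction-interval
    coverage and width; weights candidate models by Pareto-smoothed
    importance-sampling leave-one-out cross-validation and pseudo-Bayesian
    model averaging; classifies forecast windows into growth phases from
    fitted-curve landmarks; and summarises forecast error with a
    hierarchical Gamma meta-regression. Includes a calibrated synthetic
    cohort generator emulating the visit structure of a natural-history
    clinic population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
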