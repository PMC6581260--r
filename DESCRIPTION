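Package: hbifit
Title: Hierarchical Bayesian Inference for Concurrent Model Fitting and Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fits a space of candidate computational models (e.g. reinforcement
    learning choice models) to multi-subject trial-level data while treating both
    model identity and model parameters as random effects. Implements the
    hierarchical Bayesian inference (HBI) algorithm -- mean-field variational
    Bayes over a Gaussian-Gamma/Dirichlet mixture with Laplace-approximated
    subject-level posteriors -- together with the HBI t-test for group-level
    parameters, predictive fits for new subjects, exceedance and protected
    exceedance probabilities, and two reference procedures: non-hierarchical
    inference (NHI) with random-effects Bayesian model selection, and
    hierarchical parameter estimation (HPE) by expectation-maximization with
    fixed-effects comparison. Ships a library of cognitive models and bandit /
    go-no-go / two-step task simulators plus a scenario harness for recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    readr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
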