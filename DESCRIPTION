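Package: psyswitch
Title: Simulation and Analysis of Adaptive Psychophysics with Task Switching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for visuomotor decision-making experiments that combine
    fine perceptual discrimination with trial-by-trial task switching. Provides
    a Bayesian adaptive stimulus-selection engine (grid posterior over the
    psychometric parameters mu, sigma and lambda with expected-posterior-entropy
    minimization), maximum-likelihood psychometric fitting with a lapse rate and
    load-dependent noise on fixed parameter grids, ex-Gaussian reaction-time
    modelling, task-irrelevant motor output (TIMO) metrics, correlated-measures
    statistics (bootstrap confidence intervals, Sidak and Nyholt effective-test
    corrections, balanced mixed-design ANOVA), and stratified cross-validated
    logistic classification of participants. A synthetic-observer simulator with
    known ground truth makes every stage of the pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
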