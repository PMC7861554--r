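Package: ppgranger
Title: Point-Process Granger Causality for Trial-Structured Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed functional connectivity between simultaneously
    recorded neurons from trial-structured spike trains using point-process
    Granger causality. Models each neuron's conditional intensity function as
    a binomial generalized linear model on 1-ms bins, with ensemble spiking
    history covariates and, optionally, piecewise-constant exogenous
    temporal-modulation terms (G-ETM) and per-trial response-magnitude terms
    (G-ETMV). Directed influence is assessed by deviance-difference chi-square
    tests between nested fits; history and exogenous window counts are chosen
    per neuron by AIC. Includes synthetic spike-train generators
    (inhomogeneous Bernoulli-thinned point-process networks and
    integrate-and-fire networks with stochastic or fixed spike thresholds) and
    a Monte-Carlo harness that scores recovered connectivity against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
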