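Package: dirspec
Title: Directed Spectral Connectivity Between Cortical Sources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-track inference of directed connectivity between a pair of
    cortical sources recorded in two conditions (wakefulness and anaesthesia).
    The data-driven track fits multivariate autoregressive models by
    Yule-Walker estimation with BIC order selection, derives normalized
    directed transfer functions, and contrasts band-averaged values across
    conditions with rank-sum tests under false-discovery-rate control. The
    model-based track fits a two-source neural-mass generative model of the
    observed cross-spectral density by variational Laplace and compares
    hypotheses about connection architecture and condition-specific coupling
    changes with fixed-effects Bayesian model selection. Includes a synthetic
    data generator emulating intracranial recordings and degraded
    source-reconstructed observations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    Matrix,
    deSolve,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
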