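Package: mlmct
Title: Multilevel Models for Intensive Longitudinal Data with
    Heterogeneous Autoregressive Errors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-level linear mixed models for intensive longitudinal data
    (e.g. ecological momentary assessment diaries) whose within-person
    residuals follow individually heterogeneous first-order autoregressive
    processes. Implements the two-step Cholesky-transformation estimator
    (per-subject exact maximum-likelihood regression with AR(p) errors,
    whitening of outcome and design matrices by the inverse Cholesky factor
    of the fitted residual covariance, then restricted maximum-likelihood
    estimation of the multilevel model on the transformed data), the
    comparison estimators with homogeneous independent or AR(1) residual
    covariance, and a reproducible Monte Carlo study quantifying the
    relative bias of variance components and model-based standard errors
    under misspecification of the residual covariance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
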