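Package: dmtresponse
Title: Treatment-Response Prediction Models for Relapsing-Remitting
    Multiple Sclerosis Registry Data
Version: 0.1.0
Authors@R:
    person("Anna", "Keller", email = "anna.keller@example.org",
           role = c("aut", "cre"))
Description: Builds and validates personalized treatment-response
    prediction models for relapsing-remitting multiple sclerosis from
    registry-style longitudinal records. Constructs therapy cycles from
    raw therapy episodes (including no-therapy gaps and overlapping
    treatment periods), derives relapse-count and confirmed disability
    progression (CDP) outcomes, encodes the 11 baseline predictors of
    the replicated modelling strategy, fits hierarchical and
    fixed-effects generalized linear models (negative binomial with
    log-duration offset for relapse counts; binomial for CDP) with
    centre random intercepts, and evaluates them with temporal
    validation, 10-fold cross-validation, 20-bin calibration curves,
    calibration intercept and slope, C-index, MSE and RMSE%. A synthetic
    registry generator with known ground truth makes every stage
    testable without access to the original registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    lme4,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
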