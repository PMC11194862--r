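# Model-fitting tests use the cycle-level simulator so the design matrix and
# truth are exact.

fit_data <- function(cfg, n) {
  d <- generate_cycle_table(cfg, n)
  as.data.frame(d)
}

test_that("hierarchical negative binomial recovers a flat rate", {
  cfg <- flat_config(b0 = log(0.3), seed = 101)
  data <- fit_data(cfg, 3000)
  spec <- model_spec("negbinomial", n_draws = 500, seed = 1,
                     interaction_spec = interaction_spec(pairs = list()))
  fit <- fit_hierarchical(data, spec)
  se0 <- sqrt(fit$vcov["(Intercept)", "(Intercept)"])
  expect_lt(abs(fit$coef["(Intercept)"] - log(0.3)), 4 * se0)  # noise bound
  # fitted overall rate reproduces the flat truth (duration is 1 year)
  p <- predict_outcomes(fit, data)
  expect_equal(mean(p$mean), 0.3, tolerance = 0.05)
  expect_true(all(c("rhat", "ess") %in% names(fit$diagnostics)))
})

test_that("sigma_centre posterior concentrates near zero when truth is zero", {
  cfg <- flat_config(seed = 102)
  data <- fit_data(cfg, 5000)
  fit <- fit_hierarchical(data, model_spec("binomial", n_draws = 200,
                                           cdp_log_duration = FALSE))
  expect_lt(quantile(fit$draws$sigma_centre, 0.95), 0.2)
})

test_that("fixed-effects logistic fit matches the null closed forms", {
  cfg <- flat_config(p0 = 0.25, seed = 103)
  data <- fit_data(cfg, 4000)
  spec <- model_spec("binomial", cdp_log_duration = FALSE,
                     interaction_spec = interaction_spec(pairs = list()))
  fit <- fit_glm_fixed(data, spec)
  # ML logistic with intercept: average fitted probability = prevalence
  p <- predict_outcomes(fit, data)
  expect_equal(mean(p$mean), mean(data$cdp), tolerance = 1e-6)
  # null data: intercept estimates logit(prevalence)
  expect_lt(abs(fit$coef["(Intercept)"] - qlogis(0.25)),
            3.5 * sqrt(fit$vcov["(Intercept)", "(Intercept)"]))
})

test_that("fixed and hierarchical predictions agree when sigma is zero", {
  cfg <- sim_config(sigma_centre = 0, seed = 104)
  data <- fit_data(cfg, 3000)
  spec <- model_spec("negbinomial", n_draws = 500)
  ff <- fit_glm_fixed(data, spec)
  fh <- fit_hierarchical(data, spec)
  pf <- predict_outcomes(ff, data)
  ph <- predict_outcomes(fh, data)
  expect_gt(cor(pf$mean, ph$mean, method = "spearman"), 0.99)
})

test_that("prediction formulas match hand computation", {
  cfg <- sim_config(seed = 105)
  data <- fit_data(cfg, 1500)
  spec <- model_spec("negbinomial", n_draws = 300, seed = 2)
  fit <- fit_hierarchical(data, spec)
  rows <- data[1:20, ]
  p <- predict_outcomes(fit, rows, index_dmt = "natalizumab", duration = 2)
  expect_true(all(p$mean > 0))
  expect_true(all(p$outcome_free >= 0 & p$outcome_free <= 1))
  expect_true(all(p$lower <= p$mean & p$mean <= p$upper))
  # doubling duration raises expected counts, lowers relapse-free chance
  p2 <- predict_outcomes(fit, rows, index_dmt = "natalizumab", duration = 4)
  expect_true(all(p2$mean > p$mean))
  expect_true(all(p2$outcome_free < p$outcome_free))
  # relapse-free probability equals the independent pmf per fitted phi
  manual <- oracle_nb_zero(0.3, fit$theta)
  expect_equal(dmtresponse:::nb_prob_zero(0.3, fit$theta), manual,
               tolerance = 1e-12)
  expect_error(predict_outcomes(fit, rows, index_dmt = "aspirin"),
               "unknown DMT")
  expect_error(predict_outcomes(fit, rows, duration = -1), "positive")
})

test_that("binomial single-draw prediction at xb = 0 gives one half", {
  cfg <- flat_config(p0 = 0.5, seed = 106)
  data <- fit_data(cfg, 2500)
  spec <- model_spec("binomial", cdp_log_duration = FALSE, n_draws = 400)
  fit <- fit_hierarchical(data, spec)  # flat data: duration constant at 1
  refs <- default_reference_levels()
  row <- data.frame(age_cat = refs$age_cat, sex = refs$sex,
                    edss_cat = refs$edss_cat,
                    relapse_distance_cat = refs$relapse_distance_cat,
                    relapse_count_prev_year = 0, onset_distance = 0,
                    dmt_count_cat = refs$dmt_count_cat,
                    current_therapy = refs$current_therapy,
                    current_duration = 0,
                    index_therapy = refs$index_therapy,
                    second_line_prior = FALSE, duration_years = 1,
                    log_duration = 0, stringsAsFactors = FALSE)
  p <- predict_outcomes(fit, row)
  expect_equal(p$mean, 0.5, tolerance = 0.1)
  expect_equal(p$mean + p$outcome_free, 1, tolerance = 1e-12)
})

test_that("per-DMT predictions cover all six and rank a favoured DMT first", {
  br <- default_true_coefs("relapse")
  br[grepl("^index_therapy", names(br)) & !grepl(":", names(br))] <- 0.3
  br["index_therapynatalizumab"] <- -1.2
  br[grepl(":", names(br)) & grepl("index_therapy", names(br))] <- 0
  cfg <- sim_config(beta_relapse = br, seed = 107)
  data <- fit_data(cfg, 4000)
  fit <- fit_glm_fixed(data, model_spec("negbinomial"))
  all6 <- predict_all_dmts(fit, data[1:50, ], duration = 2)
  expect_equal(nrow(all6), 300)
  expect_equal(unname(table(all6$row)), rep(6L, 50), ignore_attr = TRUE)
  expect_setequal(unique(all6$index_dmt), dmt_names())
  top <- all6$index_dmt[all6$rank == 1]
  expect_equal(names(which.max(table(top))), "natalizumab")
  # zero index coefficients make the six predictions identical
  b0 <- default_true_coefs("relapse")
  cfg0 <- sim_config(seed = 108)
  data0 <- fit_data(cfg0, 500)
  fit0 <- fit_glm_fixed(data0, model_spec("negbinomial"))
  fit0$coef[grepl("index_therapy", names(fit0$coef))] <- 0
  p0 <- predict_all_dmts(fit0, data0[1:5, ], duration = 1)
  spread <- tapply(p0$mean, p0$row, function(x) diff(range(x)))
  expect_true(all(spread < 1e-12))
})

test_that("posterior MADs behave like a scale estimator", {
  cfg <- sim_config(seed = 109)
  data <- fit_data(cfg, 1500)
  fit <- fit_hierarchical(data, model_spec("negbinomial", n_draws = 500))
  m <- coefficient_mads(fit)
  expect_true(all(m >= 0))
  expect_named(m, names(fit$coef))
  # constant draws give zero MAD
  fit$draws$beta[, 1] <- 1
  expect_equal(unname(coefficient_mads(fit)[1]), 0)
  # scaled MAD of standard normal draws is ~1
  z <- matrix(rnorm(1e5), ncol = 1, dimnames = list(NULL, "z"))
  fitz <- fit; fitz$draws$beta <- z
  expect_equal(unname(coefficient_mads(fitz)), 1, tolerance = 0.02)
  # unscaled variant
  expect_equal(unname(coefficient_mads(fitz, constant = 1)),
               qnorm(0.75), tolerance = 0.02)
})

test_that("fits serialize and reload with identical predictions", {
  cfg <- sim_config(seed = 110)
  data <- fit_data(cfg, 1200)
  fit <- fit_hierarchical(data, model_spec("negbinomial", n_draws = 300))
  path <- withr::local_tempfile(fileext = ".rds")
  save_fit(fit, path)
  fit2 <- load_fit(path)
  p1 <- predict_outcomes(fit, data[1:30, ])
  p2 <- predict_outcomes(fit2, data[1:30, ])
  expect_identical(p1, p2)
})

test_that("rank-deficient designs are rejected with an explicit error", {
  cfg <- sim_config(seed = 111)
  data <- fit_data(cfg, 300)
  data$index_therapy <- factor("fingolimod", levels = levels(data$index_therapy))
  expect_error(fit_glm_fixed(data, model_spec("negbinomial")),
               "rank deficient")
})
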