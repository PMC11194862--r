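make_switch_fixture <- function(birth = "1984-01-02",  # 29.9986 y at baseline
                                onset = "2008-03-01",
                                prior_dmts = c("interferon beta1",
                                               "natalizumab")) {
  n_prior <- length(prior_dmts)
  starts <- d("2010-01-01") + (seq_len(n_prior) - 1) * 400
  ends <- starts + 360
  cycles <- data.frame(
    patient_id = "P1",
    dmt = c(prior_dmts, "NoDMT", "fingolimod"),
    start_date = c(starts, ends[n_prior], d("2014-01-01")),
    end_date = c(ends, d("2014-01-01"), d("2015-06-01")),
    censored = FALSE, flag = "ok", stringsAsFactors = FALSE)
  pairs <- data.frame(patient_id = "P1", current_dmt = "NoDMT",
                      current_start = ends[n_prior],
                      current_end = d("2014-01-01"),
                      index_dmt = "fingolimod",
                      index_start = d("2014-01-01"),
                      index_end = d("2015-06-01"), index_censored = FALSE,
                      stringsAsFactors = FALSE)
  bundle <- mini_bundle(
    patients = data.frame(patient_id = "P1", centre_id = 3L, sex = "F",
                          birth_date = d(birth), onset_date = d(onset),
                          diagnosis_date = d("2008-09-01"),
                          course_label = "RRMS", stringsAsFactors = FALSE),
    visits = data.frame(patient_id = "P1",
                        date = d(c("2013-10-01", "2014-02-01")),
                        edss = c(1.5, 4.0)),
    relapses = data.frame(patient_id = "P1",
                          date = d(c("2013-07-01", "2013-11-15"))))
  list(pairs = pairs, cycles = cycles, bundle = bundle)
}

test_that("predictors are derived and binned per the reference coding", {
  fx <- make_switch_fixture()
  f <- derive_features(fx$pairs, fx$cycles, fx$bundle)
  expect_false(f$incomplete)
  expect_equal(as.character(f$age_cat), "30 or younger")   # 30.0 years exactly
  expect_equal(as.character(f$edss_cat), "1.5 or less")    # pre-baseline 1.5
  expect_equal(as.character(f$relapse_distance_cat), "less than 0.25")
  expect_equal(f$relapse_count_prev_year, 2)
  expect_equal(as.character(f$dmt_count_cat), "2")
  expect_true(f$second_line_prior)                         # natalizumab
  expect_equal(as.character(f$current_therapy), "NoDMT")
  expect_equal(f$onset_distance,
               as.numeric(d("2014-01-01") - d("2008-03-01")) / 365.25)
  expect_equal(f$log_duration, log(f$duration_years))

  # age boundary: a hair over 30 years falls in the next bin
  fx2 <- make_switch_fixture(birth = "1983-12-28")
  f2 <- derive_features(fx2$pairs, fx2$cycles, fx2$bundle)
  expect_equal(as.character(f2$age_cat), "31 to 40")
})

test_that("never-relapsed patients get the configured distance category", {
  fx <- make_switch_fixture()
  fx$bundle$relapses <- fx$bundle$relapses[0, ]
  f <- derive_features(fx$pairs, fx$cycles, fx$bundle)
  expect_equal(as.character(f$relapse_distance_cat), "3 or more")
  expect_equal(f$relapse_count_prev_year, 0)
  f2 <- derive_features(fx$pairs, fx$cycles, fx$bundle,
                        never_relapsed_distance = "1 to 2.99")
  expect_equal(as.character(f2$relapse_distance_cat), "1 to 2.99")
})

test_that("underivable components mark the row incomplete", {
  fx <- make_switch_fixture()
  fx$bundle$visits <- fx$bundle$visits[0, ]        # no baseline EDSS
  f <- derive_features(fx$pairs, fx$cycles, fx$bundle)
  expect_true(f$incomplete)
  expect_match(f$incomplete_reason, "missing_baseline_edss")
  fx2 <- make_switch_fixture()
  fx2$pairs$current_dmt <- "OtherDMT"
  f2 <- derive_features(fx2$pairs, fx2$cycles, fx2$bundle)
  expect_true(f2$incomplete)
  expect_match(f2$incomplete_reason, "current_therapy_unsupported")
})

test_that("derivation is pure and row-order independent", {
  cfg <- quick_config(seed = 31)
  b <- generate_raw_registry(cfg)
  cycles <- add_onset_gap(build_timelines(b$therapies), b$patients)
  qf <- quality_filter(cycles, b$patients)
  el <- eligibility_filter(make_switch_pairs(qf$cycles), b$patients)
  pairs <- utils::head(el$pairs, 40)
  f1 <- derive_features(pairs, qf$cycles, b)
  f2 <- derive_features(pairs, qf$cycles, b)
  expect_identical(f1, f2)
  perm <- rev(seq_len(nrow(pairs)))
  f3 <- derive_features(pairs[perm, ], qf$cycles, b)
  rownames(f3) <- NULL
  expect_equal(f3, local({x <- f1[perm, ]; rownames(x) <- NULL; x}))
})

test_that("standardization is fit on train and reused unchanged", {
  set.seed(1)
  tr <- data.frame(current_duration = rlnorm(200), onset_distance = rnorm(200, 8),
                   relapse_count_prev_year = rpois(200, 1))
  te <- data.frame(current_duration = rlnorm(100, 1), onset_distance = rnorm(100, 5),
                   relapse_count_prev_year = rpois(100, 2))
  params <- fit_standardization(tr)
  trz <- apply_standardization(params, tr)
  for (v in params$vars) {
    expect_equal(mean(trz[[v]]), 0, tolerance = 1e-9)
    expect_equal(sd(trz[[v]]), 1, tolerance = 1e-9)
  }
  tez <- apply_standardization(params, te)
  expect_gt(max(abs(vapply(params$vars, function(v) mean(tez[[v]]),
                           numeric(1)))), 0.1)
  tr$onset_distance <- 4
  expect_error(fit_standardization(tr), "onset_distance")
})

test_that("design matrix has the documented column structure", {
  expect_length(dmtresponse:::design_colnames(interaction_spec(pairs = list())),
                29)  # intercept + 28 main-effect columns
  cols <- dmtresponse:::design_colnames(interaction_spec())
  expect_length(cols, 55)  # intercept + 54 with the default interactions
  expect_length(dmtresponse:::design_colnames(interaction_spec(),
                                              include_log_duration = TRUE),
                56)
  # an all-reference-level row is zero outside the continuous terms
  refs <- default_reference_levels()
  row <- data.frame(age_cat = refs$age_cat, sex = refs$sex,
                    edss_cat = refs$edss_cat,
                    relapse_distance_cat = refs$relapse_distance_cat,
                    relapse_count_prev_year = 0, onset_distance = 0,
                    dmt_count_cat = refs$dmt_count_cat,
                    current_therapy = refs$current_therapy,
                    current_duration = 0, index_therapy = refs$index_therapy,
                    second_line_prior = FALSE, stringsAsFactors = FALSE)
  X <- build_design_matrix(row, interaction_spec())$X
  expect_equal(sum(X != 0), 1)  # only the intercept
  expect_error(build_design_matrix(transform(row, sex = "X"),
                                   interaction_spec()),
               "unknown category")
  expect_error(interaction_spec(pairs = list(c("sex", "nonexistent"))))
  expect_error(interaction_spec(reference_levels = list(sex = "Q")))
})

test_that("the coding tables round-trip every category label", {
  lv <- feature_levels()
  for (nm in names(lv)) expect_equal(anyDuplicated(lv[[nm]]), 0)
  expect_equal(length(lv$current_therapy), 7)
  expect_equal(length(lv$index_therapy), 6)
  # each bin label is reachable exactly once from representative values
  expect_equal(as.character(dmtresponse:::bin_age(c(25, 35, 45, 60))),
               lv$age_cat)
  expect_equal(as.character(dmtresponse:::bin_edss(c(1, 2, 3.5, 8))),
               lv$edss_cat)
  expect_equal(as.character(dmtresponse:::bin_relapse_distance(
    c(0.1, 0.25, 1, 10))), lv$relapse_distance_cat)
  expect_equal(as.character(dmtresponse:::bin_dmt_count(0:3)),
               lv$dmt_count_cat)
})

test_that("default design has full column rank on a simulated cohort", {
  dcy <- generate_cycle_table(sim_config(seed = 12), 2000)
  X <- build_design_matrix(dcy, interaction_spec())$X
  expect_equal(qr(X)$rank, ncol(X))
})
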