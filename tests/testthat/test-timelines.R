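test_that("single episode maps to a single identical cycle", {
  cy <- build_timeline(episodes(c("fingolimod", "2012-01-01", "2013-01-01")))
  expect_equal(nrow(cy), 1)
  expect_equal(cy$dmt, "fingolimod")
  expect_equal(cy$start_date, d("2012-01-01"))
  expect_equal(cy$end_date, d("2013-01-01"))
})

test_that("between-therapy gaps become NoDMT cycles", {
  cy <- build_timeline(episodes(c("A", "2012-01-01", "2012-06-01"),
                                c("B", "2013-01-01", "2014-01-01")))
  expect_equal(cy$dmt, c("A", "NoDMT", "B"))
  expect_equal(cy$start_date, d(c("2012-01-01", "2012-06-01", "2013-01-01")))
  expect_equal(cy$end_date, d(c("2012-06-01", "2013-01-01", "2014-01-01")))
})

test_that("overlapping episodes yield an OtherDMT interval", {
  cy <- build_timeline(episodes(c("A", "2012-01-01", "2013-01-01"),
                                c("B", "2012-07-01", "2014-01-01")))
  expect_equal(cy$dmt, c("A", "OtherDMT", "B"))
  expect_equal(cy$start_date, d(c("2012-01-01", "2012-07-01", "2013-01-01")))
  expect_equal(cy$end_date, d(c("2012-07-01", "2013-01-01", "2014-01-01")))
})

test_that("same-DMT episodes merge across registry-granularity gaps", {
  cy <- build_timeline(episodes(c("A", "2012-01-01", "2012-06-01"),
                                c("A", "2012-06-02", "2013-01-01")))
  expect_equal(nrow(cy), 1)
  expect_equal(cy$end_date, d("2013-01-01"))
  # but a 1-day gap between different DMTs stays a NoDMT cycle
  cy2 <- build_timeline(episodes(c("A", "2012-01-01", "2012-06-01"),
                                 c("B", "2012-06-02", "2013-01-01")))
  expect_equal(cy2$dmt, c("A", "NoDMT", "B"))
})

test_that("invalid episodes pass through flagged, not silently fixed", {
  cy <- build_timeline(episodes(c("A", "2012-01-01", "2011-01-01"),
                                c("B", "2013-01-01", "2014-01-01")))
  expect_equal(sum(cy$flag == "invalid_interval"), 1)
  expect_equal(cy$dmt[cy$flag == "ok"], "B")
})

test_that("timelines partition the observed span on random episode sets", {
  set.seed(100)
  for (rep in 1:40) {
    k <- sample(1:6, 1)
    s <- sort(sample(0:2000, k))
    len <- sample(30:700, k, replace = TRUE)
    ep <- data.frame(dmt_name = sample(LETTERS[1:3], k, TRUE),
                     start_date = d("2011-01-01") + s,
                     end_date = d("2011-01-01") + s + len)
    cy <- build_timeline(ep)
    cy <- cy[cy$flag == "ok", ]
    cy <- cy[order(cy$start_date), ]
    expect_equal(cy$start_date[1], min(ep$start_date))
    expect_equal(cy$end_date[nrow(cy)], max(ep$end_date))
    if (nrow(cy) > 1)  # contiguous, non-overlapping
      expect_true(all(cy$start_date[-1] == cy$end_date[-nrow(cy)]))
    expect_true(all(cy$end_date > cy$start_date))
  }
})

test_that("quality filter removes and logs planted violations", {
  pats <- data.frame(patient_id = paste0("P", 1:10), centre_id = 1L,
                     sex = "F", birth_date = d("1980-01-01"),
                     onset_date = d("2011-06-01"),
                     diagnosis_date = d("2011-09-01"),
                     course_label = "RRMS", stringsAsFactors = FALSE)
  cycles <- data.frame(
    patient_id = paste0("P", 1:10),
    dmt = c(rep("fingolimod", 8), "mystery_drug", "natalizumab"),
    start_date = c(rep(d("2012-01-01"), 7), d("2010-01-01"),
                   rep(d("2012-01-01"), 2)),
    end_date = c(rep(d("2013-01-01"), 10)),
    censored = FALSE,
    flag = c("invalid_interval", rep("ok", 9)),
    stringsAsFactors = FALSE)
  # planted: 1 invalid interval, 1 unknown DMT, 1 start before onset
  qf <- quality_filter(cycles, pats)
  expect_equal(nrow(qf$cycles), 7)
  log <- qf$flowlog
  expect_equal(log$n_removed[log$filter_name == "invalid_interval"], 1)
  expect_equal(log$n_removed[log$filter_name == "unknown_dmt"], 1)
  expect_equal(log$n_removed[log$filter_name == "start_before_onset"], 1)
  expect_true(all(log$n_after == log$n_before - log$n_removed))
  # a fully valid set passes untouched with all-zero removals
  qf2 <- quality_filter(qf$cycles, pats)
  expect_equal(nrow(qf2$cycles), 7)
  expect_true(all(qf2$flowlog$n_removed == 0))
})

test_that("eligibility filter applies every rule and logs exact counts", {
  mk_pat <- function(id, birth = "1980-01-01", diag = "2011-09-01",
                     course = "RRMS")
    data.frame(patient_id = id, centre_id = 1L, sex = "F",
               birth_date = d(birth), onset_date = d("2011-06-01"),
               diagnosis_date = d(diag), course_label = course,
               stringsAsFactors = FALSE)
  pats <- rbind(mk_pat("ok"), mk_pat("teen", birth = "2000-06-01"),
                mk_pat("early_diag", diag = "2013-06-01"),
                mk_pat("spms", course = "SPMS"),
                mk_pat("nodates", diag = NA))
  mk_pair <- function(id, dmt = "natalizumab", start = "2013-09-01")
    data.frame(patient_id = id, current_dmt = "NoDMT",
               current_start = d("2012-01-01"), current_end = d(start),
               index_dmt = dmt, index_start = d(start),
               index_end = d("2015-01-01"), index_censored = FALSE,
               stringsAsFactors = FALSE)
  pairs <- rbind(mk_pair("ok"),
                 mk_pair("ok", dmt = "OtherDMT"),
                 mk_pair("teen"),
                 mk_pair("early_diag", start = "2013-10-01"),  # 4 months
                 mk_pair("spms"),
                 mk_pair("nodates"),
                 mk_pair("ok", start = "2010-06-01"))  # before registry
  el <- eligibility_filter(pairs, pats, registry_start = d("2011-01-01"))
  expect_equal(el$pairs$patient_id, "ok")
  log <- el$flowlog
  rule <- function(nm) log$n_removed[log$filter_name == nm]
  expect_equal(rule("index_not_6dmt"), 1)
  expect_equal(rule("age_under_18"), 1)
  expect_equal(rule("min_6_months_post_diagnosis"), 1)
  expect_equal(rule("not_rrms"), 1)
  expect_equal(rule("complete_case"), 1)
  expect_equal(rule("before_registry_start"), 1)
  expect_equal(nrow(pairs) - sum(log$n_removed), nrow(el$pairs))
})

test_that("index start exactly 6 months after diagnosis is eligible", {
  pats <- data.frame(patient_id = "P1", centre_id = 1L, sex = "F",
                     birth_date = d("1980-01-01"),
                     onset_date = d("2013-01-01"),
                     diagnosis_date = d("2013-01-01"),
                     course_label = "RRMS", stringsAsFactors = FALSE)
  base <- data.frame(patient_id = "P1", current_dmt = "NoDMT",
                     current_start = d("2013-01-01"),
                     current_end = d("2014-01-01"),
                     index_dmt = "fingolimod",
                     index_end = d("2016-01-01"), index_censored = FALSE,
                     stringsAsFactors = FALSE)
  just <- transform(base, index_start = d("2013-01-01") + ceiling(6 * 30.4375))
  short <- transform(base, index_start = d("2013-01-01") + 150)
  expect_equal(nrow(eligibility_filter(just, pats)$pairs), 1)
  expect_equal(nrow(eligibility_filter(short, pats)$pairs), 0)
})

test_that("censoring replaces open or post-cutoff ends by the last EDSS", {
  cycles <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    start_date = d(c("2015-01-01", "2015-01-01", "2015-01-01")),
    end_date = d(c("2016-05-01", NA, NA)),
    censored = FALSE, stringsAsFactors = FALSE)
  visits <- data.frame(
    patient_id = c("P1", "P2", "P2", "P3"),
    date = d(c("2016-06-01", "2016-11-03", "2017-02-01", "2014-12-01")),
    edss = c(2, 2, 2.5, 1))
  cz <- censor_at_last_edss(cycles, visits, d("2017-01-01"))
  out <- cz$cycles
  # closed pre-cutoff cycle untouched
  expect_equal(out$end_date[out$patient_id == "P1"], d("2016-05-01"))
  expect_false(out$censored[out$patient_id == "P1"])
  # open cycle censored at last pre-cutoff measurement
  expect_equal(out$end_date[out$patient_id == "P2"], d("2016-11-03"))
  expect_true(out$censored[out$patient_id == "P2"])
  # open cycle with no usable EDSS dropped and logged
  expect_false("P3" %in% out$patient_id)
  expect_equal(cz$flowlog$n_removed, 1)
})

test_that("one random pair per patient, uniform and seed-stable", {
  pairs <- do.call(rbind, lapply(sprintf("P%04d", 1:1000), function(id)
    data.frame(patient_id = id, current_dmt = "NoDMT",
               current_start = d("2012-01-01"),
               current_end = d("2013-01-01"),
               index_dmt = c("fingolimod", "natalizumab"),
               index_start = d(c("2013-01-01", "2014-06-01")),
               index_end = d(c("2014-06-01", "2016-01-01")),
               index_censored = FALSE, stringsAsFactors = FALSE)))
  sel <- select_one_cycle_per_patient(pairs, seed = 7)
  expect_equal(nrow(sel), 1000)
  expect_equal(anyDuplicated(sel$patient_id), 0)
  # binomial 99% interval around 0.5 for n = 1000
  frac_first <- mean(sel$index_dmt == "fingolimod")
  expect_lt(abs(frac_first - 0.5), 2.58 * sqrt(0.25 / 1000))
  expect_identical(select_one_cycle_per_patient(pairs, seed = 7), sel)
  one <- pairs[pairs$patient_id == "P0001" & pairs$index_dmt == "fingolimod", ]
  expect_equal(nrow(select_one_cycle_per_patient(one, seed = 1)), 1)
})

test_that("temporal split uses the declared strict-before boundary", {
  pairs <- data.frame(patient_id = c("A", "B"), current_dmt = "NoDMT",
                      current_start = d("2012-01-01"),
                      current_end = d("2013-01-01"),
                      index_dmt = "fingolimod",
                      index_start = d(c("2016-12-31", "2017-01-01")),
                      index_end = d("2018-01-01"), index_censored = FALSE,
                      stringsAsFactors = FALSE)
  sp <- temporal_split(pairs, d("2017-01-01"))
  expect_equal(sp$train$patient_id, "A")
  expect_equal(sp$test$patient_id, "B")
  expect_length(intersect(sp$train$patient_id, sp$test$patient_id), 0)
  empty <- temporal_split(pairs[0, ], d("2017-01-01"))
  expect_equal(nrow(empty$train) + nrow(empty$test), 0)
  allpre <- temporal_split(pairs[1, ], d("2019-07-01"))
  expect_equal(nrow(allpre$test), 0)
})
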