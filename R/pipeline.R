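# Pipeline driver: configuration, stage orchestration, artifact I/O.

#' Pipeline configuration
#'
#' Collects every stage's settings and the toggles for the declared
#' modelling conventions. Unknown arguments are rejected.
#'
#' @param sim A [sim_config()] used when no input directory is given.
#' @param in_dir Optional directory with an existing registry bundle
#'   (four CSV files, as written by [write_registry()]).
#' @param split_date Temporal split date (main analysis 2017-01-01;
#'   sensitivity 2019-07-01).
#' @param registry_start Registry foundation date for eligibility.
#' @param extraction_date Data extraction date; ongoing cycles are censored
#'   at the last EDSS measurement before it.
#' @param seed Seed for cycle selection and cross-validation folds.
#' @param engine `"fixed"` or `"hierarchical"`.
#' @param relapse_spec,cdp_spec [model_spec()]s for the two outcomes.
#' @param k Cross-validation folds.
#' @param n_bins Calibration bins.
#' @param cindex_B Bootstrap resamples for C-index CIs.
#' @param sustain Sustainment rule for progression detection
#'   (`"threshold"` or `"candidate"`).
#' @param never_relapsed_distance Relapse-distance category for
#'   never-relapsed patients.
#' @param merge_gap_days Same-DMT merge tolerance in the timeline builder.
#' @param run_cv Run the 10-fold cross-validation (slowest stage).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            in_dir = NULL,
                            split_date = as.Date("2017-01-01"),
                            registry_start = as.Date("2011-01-01"),
                            extraction_date = NULL,
                            seed = 1L,
                            engine = c("fixed", "hierarchical"),
                            relapse_spec = model_spec("negbinomial"),
                            cdp_spec = model_spec("binomial"),
                            k = 10L, n_bins = 20L, cindex_B = 500L,
                            sustain = "threshold",
                            never_relapsed_distance = "3 or more",
                            merge_gap_days = 1,
                            run_cv = TRUE) {
  engine <- match.arg(engine)
  extraction_date <- as_date(extraction_date %||% sim$study_window[2])
  structure(list(sim = sim, in_dir = in_dir,
                 split_date = as_date(split_date),
                 registry_start = as_date(registry_start),
                 extraction_date = extraction_date,
                 seed = as.integer(seed), engine = engine,
                 relapse_spec = relapse_spec, cdp_spec = cdp_spec,
                 k = as.integer(k), n_bins = as.integer(n_bins),
                 cindex_B = as.integer(cindex_B), sustain = sustain,
                 never_relapsed_distance = never_relapsed_distance,
                 merge_gap_days = merge_gap_days, run_cv = run_cv),
            class = "pipeline_config")
}

analysis_rows <- function(features, outcomes) {
  stopifnot(nrow(features) == nrow(outcomes))
  cbind(features[!features$incomplete, , drop = FALSE],
        outcomes[!features$incomplete,
                 c("relapse_count", "cdp"), drop = FALSE])
}

#' Run the full pipeline
#'
#' Simulate (or load) a registry, build and filter therapy timelines, form
#' and select switch pairs, censor, split temporally, derive outcomes and
#' features, fit both outcome models, and evaluate them by cross-validation
#' and temporal validation. Every filter step is logged in a participant
#' flow log; all artifacts are returned and, if `out_dir` is given, written
#' to CSV/JSON files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for artifacts (`cycles.csv`,
#'   `pairs.csv`, `features.csv`, `outcomes.csv`, `flowlog.json`,
#'   `report.json`, calibration tables).
#' @return List with the registry bundle, cycle and pair tables, flow log,
#'   train/test analysis sets, fits and `metrics` (per outcome and scheme).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- if (!is.null(config$in_dir)) read_registry(config$in_dir)
            else generate_raw_registry(config$sim)
  flow <- flowlog_new()
  stage <- function(log, prefix) {
    log$filter_name <- paste0(prefix, ":", log$filter_name)
    rbind(flow, log)
  }

  cycles <- build_timelines(bundle$therapies, config$merge_gap_days)
  cycles <- add_onset_gap(cycles, bundle$patients)
  qf <- quality_filter(cycles, bundle$patients)
  flow <- stage(qf$flowlog, "quality")
  cz <- censor_at_last_edss(qf$cycles, bundle$visits, config$extraction_date)
  flow <- stage(cz$flowlog, "extraction_censoring")

  pairs <- make_switch_pairs(cz$cycles)
  el <- eligibility_filter(pairs, bundle$patients, config$registry_start)
  flow <- stage(el$flowlog, "eligibility")
  sel <- select_one_cycle_per_patient(el$pairs, config$seed)
  flow <- stage(flowlog_add(flowlog_new(), "one_cycle_per_patient",
                            nrow(el$pairs), nrow(sel)), "selection")
  sp <- temporal_split(sel, config$split_date)
  flow <- stage(flowlog_add(flowlog_new(), "train", nrow(sel), nrow(sp$train)),
                "temporal_split")
  flow <- stage(flowlog_add(flowlog_new(), "test", nrow(sel), nrow(sp$test)),
                "temporal_split")

  # training follow-up is additionally censored before the split date to
  # prevent temporal overlap with the test set
  tc <- censor_at_last_edss(sp$train, bundle$visits, config$split_date,
                            start_col = "index_start",
                            end_col = "index_end",
                            censored_col = "index_censored")
  flow <- stage(tc$flowlog, "train_split_censoring")
  train_pairs <- tc$cycles
  test_pairs <- sp$test

  build_set <- function(pairs_) {
    if (nrow(pairs_) == 0) return(NULL)
    feats <- derive_features(pairs_, qf$cycles, bundle,
                             config$never_relapsed_distance)
    outs <- derive_outcomes(pairs_, bundle, config$sustain)
    analysis_rows(feats, outs)
  }
  train <- build_set(train_pairs)
  test <- build_set(test_pairs)
  flow <- stage(flowlog_add(flowlog_new(), "complete_case_train",
                            nrow(train_pairs), NROW(train)), "features")
  flow <- stage(flowlog_add(flowlog_new(), "complete_case_test",
                            nrow(test_pairs), NROW(test)), "features")
  if (is.null(train) || nrow(train) < 50)
    stop("training set too small after filtering (",
         NROW(train), " rows)", call. = FALSE)

  std <- fit_standardization(train)
  fit_one <- function(spec) {
    if (config$engine == "fixed") fit_glm_fixed(train, spec, std)
    else fit_hierarchical(train, spec, std)
  }
  fits <- list(relapse = fit_one(config$relapse_spec),
               cdp = fit_one(config$cdp_spec))

  metrics <- list()
  dfree <- length(fits$relapse$coef) - 1L
  for (outc in c("relapse", "cdp")) {
    spec <- if (outc == "relapse") config$relapse_spec else config$cdp_spec
    fam <- if (outc == "relapse") "count" else "binary"
    obs_col <- if (outc == "relapse") "relapse_count" else "cdp"
    if (isTRUE(config$run_cv)) {
      cv <- kfold_oos_predictions(train, spec, k = config$k,
                                  seed = config$seed, engine = config$engine)
      metrics[[paste0(outc, "_cv")]] <- metrics_report(
        cv$mean, as.numeric(train[[obs_col]]), cv$outcome_free,
        family = fam, scheme = "cv", df = dfree, n_bins = config$n_bins,
        group = train$index_therapy, cindex_B = config$cindex_B,
        seed = config$seed)
    }
    if (!is.null(test) && nrow(test) >= config$n_bins) {
      fit <- fits[[outc]]
      p <- predict_outcomes(fit, test)
      metrics[[paste0(outc, "_temporal")]] <- metrics_report(
        p$mean, as.numeric(test[[obs_col]]), p$outcome_free,
        family = fam, scheme = "temporal", df = dfree,
        n_bins = config$n_bins, group = test$index_therapy,
        cindex_B = config$cindex_B, seed = config$seed)
    }
  }

  result <- list(bundle = bundle, cycles = qf$cycles, pairs = sel,
                 flowlog = flow, train = train, test = test,
                 standardization = std, fits = fits, metrics = metrics)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, out_dir, config)
  invisible(result)
}

strip_bins <- function(report) {
  report$calibration_bins <- NULL
  unclass(report)
}

#' @rdname run_pipeline
#' @param result A `run_pipeline()` result.
#' @export
write_pipeline_artifacts <- function(result, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, nm) {
    if (!is.null(x))
      utils::write.csv(x, file.path(out_dir, nm), row.names = FALSE)
  }
  wr(result$cycles, "cycles.csv")
  wr(result$pairs, "pairs.csv")
  drop_cols <- function(d) d[, setdiff(names(d), "incomplete_reason")]
  if (!is.null(result$train)) wr(drop_cols(result$train), "features_train.csv")
  if (!is.null(result$test)) wr(drop_cols(result$test), "features_test.csv")
  jsonlite::write_json(result$flowlog, file.path(out_dir, "flowlog.json"),
                       auto_unbox = TRUE, digits = NA)
  report <- lapply(result$metrics, strip_bins)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (nm in names(result$metrics)) {
    b <- result$metrics[[nm]]$calibration_bins
    tab <- if (is.data.frame(b)) b else b$overall
    wr(tab, paste0("calibration_", nm, ".csv"))
  }
  invisible(out_dir)
}
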