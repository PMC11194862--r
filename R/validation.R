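# Performance battery: out-of-sample cross-validation, C-index, MSE/RMSE%,
# 20-bin calibration curves with intercept and slope, events per variable,
# and MAD rank agreement.

#' Out-of-sample predictions by k-fold cross-validation
#'
#' Splits rows (one per patient) into `k` folds of near-equal size; each
#' row's prediction comes from a model fit that excludes its fold, with the
#' continuous-predictor standardization refit inside each training fold.
#'
#' @param data Analysis rows (complete features plus outcome columns).
#' @param spec A [model_spec()].
#' @param k Number of folds (default 10).
#' @param seed Seed controlling the fold assignment.
#' @param engine `"fixed"` (fixed-effects GLM) or `"hierarchical"`.
#' @param standardize Refit train-fold standardization (default `TRUE`).
#' @return Data frame aligned with `data`: `fold`, predicted `mean`,
#'   `outcome_free`.
#' @export
kfold_oos_predictions <- function(data, spec, k = 10L, seed = 1L,
                                  engine = c("fixed", "hierarchical"),
                                  standardize = TRUE) {
  engine <- match.arg(engine)
  n <- nrow(data)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of rows", call. = FALSE)
  fold <- with_local_seed(seed, sample(rep_len(seq_len(k), n)))
  out <- data.frame(fold = fold, mean = NA_real_, outcome_free = NA_real_)
  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    std <- if (standardize) fit_standardization(train) else NULL
    fit <- if (engine == "fixed") fit_glm_fixed(train, spec, std)
           else fit_hierarchical(train, spec, std)
    p <- predict_outcomes(fit, test)
    out$mean[fold == f] <- p$mean
    out$outcome_free[fold == f] <- p$outcome_free
  }
  out
}

#' Concordance index with bootstrap confidence interval
#'
#' Over all pairs with unequal observed outcomes, the fraction in which the
#' larger observation received the larger prediction; pairs with tied
#' predictions count one half. The confidence interval is a seeded
#' nonparametric percentile bootstrap.
#'
#' @param pred,obs Numeric vectors of equal length.
#' @param conf Compute the bootstrap CI (set `FALSE` for the estimate only).
#' @param B Number of bootstrap resamples.
#' @param seed Bootstrap seed.
#' @param level Confidence level.
#' @return List with `estimate`, `lower`, `upper`.
#' @export
c_index <- function(pred, obs, conf = TRUE, B = 2000L, seed = 1L,
                    level = 0.95) {
  stopifnot(length(pred) == length(obs), length(obs) >= 2)
  if (length(unique(obs)) < 2)
    stop("C-index undefined: all observations are equal", call. = FALSE)
  est <- unname(survival::concordance(obs ~ pred)$concordance)
  if (!conf) return(list(estimate = est, lower = NA_real_, upper = NA_real_))
  n <- length(obs)
  stats_ <- with_local_seed(seed, {
    vapply(seq_len(B), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(obs[idx])) >= 2) break
      }
      unname(survival::concordance(obs[idx] ~ pred[idx])$concordance)
    }, numeric(1))
  })
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(stats_, c(a, 1 - a)))
  list(estimate = est, lower = ci[1], upper = ci[2])
}

#' Mean squared error and relative root-MSE percentage
#'
#' `rmse_pct` expresses the root-MSE relative to the population standard
#' deviation of the observed outcomes, in percent (for binary outcomes the
#' MSE is the Brier score).
#'
#' @param pred,obs Numeric vectors of equal length (n >= 2).
#' @return `mse`: a single number; `rmse_pct`: a percentage.
#' @export
mse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(obs) >= 2)
  mean((pred - obs)^2)
}

#' @rdname mse
#' @export
rmse_pct <- function(pred, obs) {
  m <- mse(pred, obs)
  sd_pop <- sqrt(mean((obs - mean(obs))^2))
  if (sd_pop == 0)
    stop("RMSE% undefined: observed outcomes have zero variance",
         call. = FALSE)
  100 * sqrt(m) / sd_pop
}

#' Equally-populated calibration bins
#'
#' Rows are sorted by prediction (stable order for ties) and split into
#' `n_bins` contiguous bins whose sizes differ by at most one; remainder
#' rows go to the lowest bins. Optionally also computed within groups
#' (e.g. per index DMT).
#'
#' @param pred,obs Numeric vectors.
#' @param n_bins Number of bins (default 20).
#' @param group Optional grouping vector for per-group tables.
#' @return Data frame `bin`, `n`, `mean_pred`, `mean_obs`; with `group`, a
#'   list with `overall` and `by_group`.
#' @export
calibration_bins <- function(pred, obs, n_bins = 20L, group = NULL) {
  stopifnot(length(pred) == length(obs))
  n <- length(pred)
  if (n < n_bins)
    stop("need at least n_bins observations", call. = FALSE)
  ord <- order(pred)                      # radix: stable for ties
  sizes <- rep(n %/% n_bins, n_bins) + (seq_len(n_bins) <= n %% n_bins)
  bin <- factor(rep(seq_len(n_bins), times = sizes),
                levels = seq_len(n_bins))
  tab <- data.frame(bin = seq_len(n_bins), n = sizes,
                    mean_pred = as.numeric(tapply(pred[ord], bin, mean)),
                    mean_obs = as.numeric(tapply(obs[ord], bin, mean)))
  if (is.null(group)) return(tab)
  by_group <- lapply(split(seq_len(n), group), function(idx) {
    nb <- min(n_bins, length(idx))
    calibration_bins(pred[idx], obs[idx], nb)
  })
  list(overall = tab, by_group = by_group)
}

#' Calibration intercept and slope
#'
#' Binary outcomes use the logistic recalibration framework: the slope is
#' the coefficient of `logit(pred)` in a logistic regression of the
#' observations, and the intercept comes from a logistic regression with
#' `logit(pred)` as a fixed offset. Count outcomes use weighted least
#' squares of bin-mean observed on bin-mean predicted over the calibration
#' bins (weights = bin sizes); `level = "rows"` selects the row-level
#' alternative. Confidence intervals are Wald intervals from the respective
#' model standard errors.
#'
#' @param pred,obs Numeric vectors.
#' @param family `"binary"` or `"count"`.
#' @param n_bins Bins for the count-family line.
#' @param level `"bins"` (default) or `"rows"` for the count family.
#' @param clip Probability clipping bounds for the logit.
#' @return List with `intercept` and `slope`, each `c(estimate, lower,
#'   upper)`.
#' @export
calibration_line <- function(pred, obs, family = c("binary", "count"),
                             n_bins = 20L, level = c("bins", "rows"),
                             clip = 1e-6) {
  family <- match.arg(family); level <- match.arg(level)
  ci <- function(est, se) c(estimate = est, lower = est - 1.96 * se,
                            upper = est + 1.96 * se)
  if (family == "binary") {
    lp <- stats::qlogis(pmin(pmax(pred, clip), 1 - clip))
    if (stats::var(lp) == 0)
      stop("degenerate predictions: calibration slope undefined",
           call. = FALSE)
    sl <- stats::glm(obs ~ lp, family = stats::binomial())
    it <- stats::glm(obs ~ 1, offset = lp, family = stats::binomial())
    s <- summary(sl)$coefficients; i <- summary(it)$coefficients
    list(intercept = ci(i[1, 1], i[1, 2]), slope = ci(s[2, 1], s[2, 2]))
  } else {
    if (level == "bins") {
      b <- calibration_bins(pred, obs, n_bins)
      fit <- stats::lm(mean_obs ~ mean_pred, data = b, weights = b$n)
    } else {
      fit <- stats::lm(obs ~ pred)
    }
    co <- summary(fit)$coefficients
    list(intercept = ci(co[1, 1], co[1, 2]), slope = ci(co[2, 1], co[2, 2]))
  }
}

#' Events per variable
#'
#' @param n_events Number of outcome events.
#' @param df Model degrees of freedom (>= 1).
#' @return `n_events / df`.
#' @export
events_per_variable <- function(n_events, df) {
  if (df < 1) stop("df must be at least 1", call. = FALSE)
  n_events / df
}

#' Spearman rank correlation between two MAD vectors
#'
#' Matches coefficients by name (at least 3 shared) and computes the
#' Spearman correlation with ties mid-ranked.
#'
#' @param mads_a,mads_b Named numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
mad_spearman <- function(mads_a, mads_b) {
  shared <- intersect(names(mads_a), names(mads_b))
  if (length(shared) < 3)
    stop("need at least 3 shared coefficient names", call. = FALSE)
  stats::cor(mads_a[shared], mads_b[shared], method = "spearman")
}

#' Assemble a metrics report
#'
#' The full performance summary for one outcome under one validation scheme:
#' C-index with CI, MSE, RMSE%, calibration intercept/slope with CIs, the
#' calibration table, prediction and observation summaries, and events per
#' variable.
#'
#' @param pred Predicted mean outcome per row.
#' @param obs Observed outcome per row.
#' @param outcome_free Predicted outcome-free probability per row (optional,
#'   for the outcome-free summary).
#' @param family `"binary"` or `"count"`.
#' @param scheme Label, e.g. `"cv"` or `"temporal"`.
#' @param df Model degrees of freedom (for events per variable; the number
#'   of events is `sum(obs > 0)`).
#' @param n_bins Calibration bins.
#' @param group Optional per-row grouping (index DMT) for per-DMT bins.
#' @param cindex_B,seed Bootstrap settings for the C-index CI.
#' @return List of class `metrics_report`.
#' @export
metrics_report <- function(pred, obs, outcome_free = NULL,
                           family = c("binary", "count"), scheme = "temporal",
                           df = NULL, n_bins = 20L, group = NULL,
                           cindex_B = 2000L, seed = 1L) {
  family <- match.arg(family)
  ci <- c_index(pred, obs, B = cindex_B, seed = seed)
  bins <- calibration_bins(pred, obs, n_bins, group = group)
  line <- calibration_line(pred, obs, family, n_bins)
  n_events <- sum(obs > 0)
  structure(list(
    scheme = scheme, family = family, n = length(obs),
    c_index = ci,
    mse = mse(pred, obs),
    rmse_pct = rmse_pct(pred, obs),
    calibration_intercept = line$intercept,
    calibration_slope = line$slope,
    calibration_bins = bins,
    predicted = list(mean = mean(pred), range = range(pred)),
    observed = list(mean = mean(obs), range = range(obs)),
    outcome_free_predicted = if (!is.null(outcome_free))
      mean(outcome_free) else NULL,
    outcome_free_observed = mean(obs == 0),
    n_events = n_events,
    df = df,
    events_per_variable = if (!is.null(df))
      events_per_variable(n_events, df) else NULL),
    class = "metrics_report")
}
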