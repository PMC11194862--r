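# Baseline predictor derivation, coding, standardization and design matrix.
#
# The model uses 11 predictors assessed at baseline (the start of the index
# therapy): age, sex, baseline EDSS, time since last relapse, relapse count in
# the previous year, time since disease onset, number of prior DMTs, current
# therapy and its duration, index therapy, and prior second-line exposure.

AGE_LEVELS  <- c("30 or younger", "31 to 40", "41 to 50", "51 or older")
EDSS_LEVELS <- c("1.5 or less", "2 to 2.5", "3 to 3.5", "4 to 10")
RELAPSE_DISTANCE_LEVELS <- c("less than 0.25", "0.25 to 0.99",
                             "1 to 2.99", "3 or more")
DMT_COUNT_LEVELS <- c("0", "1", "2", "3 or more")
SEX_LEVELS <- c("F", "M")
CURRENT_THERAPY_LEVELS <- c(DMT6, NO_DMT)
INDEX_THERAPY_LEVELS <- DMT6

# Continuous predictors standardized by default (train-set mean/SD).
DEFAULT_CONTINUOUS <- c("current_duration", "onset_distance",
                        "relapse_count_prev_year")

#' Category levels used by the predictor coding
#'
#' @return Named list of the category labels for every categorical predictor.
#' @export
feature_levels <- function() {
  list(age_cat = AGE_LEVELS,
       sex = SEX_LEVELS,
       edss_cat = EDSS_LEVELS,
       relapse_distance_cat = RELAPSE_DISTANCE_LEVELS,
       dmt_count_cat = DMT_COUNT_LEVELS,
       current_therapy = CURRENT_THERAPY_LEVELS,
       index_therapy = INDEX_THERAPY_LEVELS)
}

bin_age <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 30, 40, 50, Inf), labels = AGE_LEVELS,
      right = TRUE)
}

bin_edss <- function(edss) {
  # EDSS moves in 0.5 steps, so the printed labels give unambiguous breaks.
  cut(edss, breaks = c(-Inf, 1.5, 2.5, 3.5, 10), labels = EDSS_LEVELS,
      right = TRUE)
}

bin_relapse_distance <- function(years) {
  cut(years, breaks = c(-Inf, 0.25, 1, 3, Inf), labels = RELAPSE_DISTANCE_LEVELS,
      right = FALSE)
}

bin_dmt_count <- function(k) {
  cut(k, breaks = c(-Inf, 0, 1, 2, Inf), labels = DMT_COUNT_LEVELS,
      right = TRUE)
}

#' Derive baseline predictors for switch pairs
#'
#' Computes the 11 predictors for every current/index therapy pair, assessed
#' on or before baseline (the index therapy start). Rows for which any
#' component is underivable (e.g. no baseline EDSS, current therapy not one of
#' the supported labels) are flagged `incomplete` with a reason; they flow to
#' complete-case removal rather than raising an error.
#'
#' Never-relapsed patients receive relapse distance "3 or more" and a
#' previous-year relapse count of 0 (configurable via
#' `never_relapsed_distance`).
#'
#' @param pairs Switch-pair table from [make_switch_pairs()].
#' @param cycles Full therapy-cycle table (used to count prior DMTs).
#' @param bundle Registry bundle with `patients`, `visits`, `relapses`.
#' @param never_relapsed_distance Category assigned when no prior relapse is
#'   recorded.
#' @return Data frame with one row per pair: the predictor columns, the
#'   log-duration offset, outcome-independent identifiers, and
#'   `incomplete`/`incomplete_reason`.
#' @export
derive_features <- function(pairs, cycles, bundle,
                            never_relapsed_distance = "3 or more") {
  stopifnot(never_relapsed_distance %in% RELAPSE_DISTANCE_LEVELS)
  patients <- bundle$patients
  visits_by  <- split(bundle$visits, bundle$visits$patient_id)
  relapse_by <- split(bundle$relapses, bundle$relapses$patient_id)
  cycles_by  <- split(cycles, cycles$patient_id)
  pat_idx <- match(pairs$patient_id, patients$patient_id)

  n <- nrow(pairs)
  out <- data.frame(
    patient_id = pairs$patient_id,
    centre_id = patients$centre_id[pat_idx],
    age_cat = factor(rep(NA_character_, n), levels = AGE_LEVELS),
    sex = factor(patients$sex[pat_idx], levels = SEX_LEVELS),
    edss_cat = factor(rep(NA_character_, n), levels = EDSS_LEVELS),
    relapse_distance_cat = factor(rep(NA_character_, n),
                                  levels = RELAPSE_DISTANCE_LEVELS),
    relapse_count_prev_year = NA_real_,
    onset_distance = NA_real_,
    dmt_count_cat = factor(rep(NA_character_, n), levels = DMT_COUNT_LEVELS),
    current_therapy = factor(rep(NA_character_, n),
                             levels = CURRENT_THERAPY_LEVELS),
    current_duration = NA_real_,
    index_therapy = factor(as.character(pairs$index_dmt),
                           levels = INDEX_THERAPY_LEVELS),
    second_line_prior = NA,
    index_start = as_date(pairs$index_start),
    index_end = as_date(pairs$index_end),
    duration_years = NA_real_,
    log_duration = NA_real_,
    incomplete = FALSE,
    incomplete_reason = NA_character_,
    stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    pid <- pairs$patient_id[i]
    baseline <- as_date(pairs$index_start[i])
    pat <- patients[pat_idx[i], ]
    reasons <- character(0)

    if (is.na(pat$birth_date) || is.na(pat$onset_date)) {
      reasons <- c(reasons, "missing_dates")
    } else {
      out$age_cat[i] <- bin_age(years_between(as_date(pat$birth_date), baseline))
      out$onset_distance[i] <- years_between(as_date(pat$onset_date), baseline)
    }
    if (is.na(out$sex[i])) reasons <- c(reasons, "missing_sex")

    v <- visits_by[[pid]]
    b_edss <- if (is.null(v)) NA_real_ else
      baseline_edss(v$date, v$edss, baseline)
    if (is.na(b_edss)) reasons <- c(reasons, "missing_baseline_edss")
    else out$edss_cat[i] <- bin_edss(b_edss)

    r <- relapse_by[[pid]]
    rdates <- if (is.null(r)) as.Date(character(0)) else as_date(r$date)
    prior <- rdates[rdates <= baseline]
    if (length(prior) == 0) {
      out$relapse_distance_cat[i] <- never_relapsed_distance
      out$relapse_count_prev_year[i] <- 0
    } else {
      out$relapse_distance_cat[i] <-
        bin_relapse_distance(years_between(max(prior), baseline))
      out$relapse_count_prev_year[i] <-
        sum(prior > baseline - DAYS_PER_YEAR)
    }

    cyc <- cycles_by[[pid]]
    prior_dmts <- if (is.null(cyc)) character(0) else
      setdiff(unique(as.character(
        cyc$dmt[as_date(cyc$start_date) < baseline])),
        c(NO_DMT, OTHER_DMT))
    out$dmt_count_cat[i] <- bin_dmt_count(length(prior_dmts))
    out$second_line_prior[i] <- any(prior_dmts %in% SECOND_LINE_DMTS)

    cur <- as.character(pairs$current_dmt[i])
    if (cur %in% CURRENT_THERAPY_LEVELS) {
      out$current_therapy[i] <- cur
      cd <- years_between(as_date(pairs$current_start[i]),
                          as_date(pairs$current_end[i]))
      if (is.finite(cd) && cd > 0) out$current_duration[i] <- cd
      else reasons <- c(reasons, "nonpositive_current_duration")
    } else {
      reasons <- c(reasons, "current_therapy_unsupported")
    }

    d <- years_between(baseline, as_date(pairs$index_end[i]))
    if (is.finite(d) && d > 0) {
      out$duration_years[i] <- d
      out$log_duration[i] <- log(d)
    } else {
      reasons <- c(reasons, "nonpositive_index_duration")
    }

    if (length(reasons)) {
      out$incomplete[i] <- TRUE
      out$incomplete_reason[i] <- paste(unique(reasons), collapse = ";")
    }
  }
  out
}

#' Train-set standardization parameters
#'
#' Means and standard deviations of the continuous predictors, computed on
#' the training rows only; [apply_standardization()] then reuses them
#' unchanged on any row set (in particular the test set).
#'
#' @param train_rows Feature rows (training set).
#' @param vars Continuous predictors to standardize.
#' @return Object of class `standardization_params`.
#' @export
fit_standardization <- function(train_rows, vars = DEFAULT_CONTINUOUS) {
  stopifnot(nrow(train_rows) > 0, all(vars %in% names(train_rows)))
  mu <- vapply(vars, function(v) mean(train_rows[[v]]), numeric(1))
  sd_ <- vapply(vars, function(v) stats::sd(train_rows[[v]]), numeric(1))
  zero <- vars[!is.finite(sd_) | sd_ <= 0]
  if (length(zero))
    stop("zero or undefined SD for predictor(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  structure(list(vars = vars, mean = mu, sd = sd_),
            class = "standardization_params")
}

#' @rdname fit_standardization
#' @param params A `standardization_params` object.
#' @param rows Feature rows to transform.
#' @export
apply_standardization <- function(params, rows) {
  stopifnot(inherits(params, "standardization_params"))
  for (v in params$vars)
    rows[[v]] <- (rows[[v]] - params$mean[[v]]) / params$sd[[v]]
  rows
}

#' Interaction specification for the design matrix
#'
#' The default term set adds treatment interactions to the 11 main effects:
#' current therapy x current duration, index therapy x previous-year relapse
#' count, and index therapy x relapse distance, for 54 non-intercept columns.
#' Reference levels default to the most frequent training categories and are
#' overridable.
#'
#' @param pairs List of 2-element character vectors naming interacting
#'   predictors.
#' @param reference_levels Named list category -> reference level.
#' @return Object of class `interaction_spec`.
#' @export
interaction_spec <- function(pairs = list(
                               c("current_therapy", "current_duration"),
                               c("index_therapy", "relapse_count_prev_year"),
                               c("index_therapy", "relapse_distance_cat")),
                             reference_levels = default_reference_levels()) {
  known <- c(names(feature_levels()), DEFAULT_CONTINUOUS, "log_duration",
             "second_line_prior")
  for (p in pairs)
    if (length(p) != 2 || !all(p %in% known))
      stop("interaction pair must name two known predictors: ",
           paste(p, collapse = " x "), call. = FALSE)
  lv <- feature_levels()
  for (nm in names(reference_levels))
    if (!reference_levels[[nm]] %in% lv[[nm]])
      stop("invalid reference level for ", nm, ": ", reference_levels[[nm]],
           call. = FALSE)
  structure(list(pairs = pairs, reference_levels = reference_levels),
            class = "interaction_spec")
}

#' @rdname interaction_spec
#' @export
default_reference_levels <- function() {
  list(age_cat = "31 to 40",            # most frequent training category
       sex = "F",
       edss_cat = "1.5 or less",
       relapse_distance_cat = "0.25 to 0.99",
       dmt_count_cat = "1",
       current_therapy = NO_DMT,
       index_therapy = "fingolimod")
}

#' Reference levels chosen as the most frequent category per factor
#'
#' @param rows Feature rows (typically the training set).
#' @return Named list usable as `reference_levels` in [interaction_spec()].
#' @export
modal_reference_levels <- function(rows) {
  lv <- feature_levels()
  out <- lapply(names(lv), function(nm) {
    tab <- table(factor(rows[[nm]], levels = lv[[nm]]))
    names(tab)[which.max(tab)]
  })
  names(out) <- names(lv)
  out
}

MAIN_EFFECT_TERMS <- c("age_cat", "sex", "edss_cat", "relapse_distance_cat",
                       "relapse_count_prev_year", "onset_distance",
                       "dmt_count_cat", "current_therapy", "current_duration",
                       "index_therapy", "second_line_prior")

#' Build the model design matrix
#'
#' Dummy (treatment-vs-reference) coding for every categorical predictor,
#' plus one product block per interaction pair. Column order and names are
#' deterministic given the specification.
#'
#' @param rows Complete feature rows.
#' @param spec An [interaction_spec()].
#' @param include_log_duration Add `log_duration` as a fixed-effect column
#'   (used by the CDP model, which has no offset).
#' @return List with `X` (numeric matrix including the intercept column) and
#'   `colnames`.
#' @export
build_design_matrix <- function(rows, spec = interaction_spec(),
                                include_log_duration = FALSE) {
  stopifnot(inherits(spec, "interaction_spec"))
  lv <- feature_levels()
  d <- rows
  for (nm in names(lv)) {
    f <- factor(as.character(d[[nm]]), levels = lv[[nm]])
    if (anyNA(f) && !anyNA(d[[nm]]))
      stop("unknown category in '", nm, "'", call. = FALSE)
    if (anyNA(f))
      stop("missing value in '", nm, "'; rows must be complete", call. = FALSE)
    ref <- spec$reference_levels[[nm]] %||% lv[[nm]][1]
    d[[nm]] <- stats::relevel(f, ref = ref)
  }
  d$second_line_prior <- as.logical(d$second_line_prior)
  fml <- stats::reformulate(c(sprintf("`%s`", MAIN_EFFECT_TERMS),
                              if (include_log_duration) "log_duration",
                              vapply(spec$pairs, function(p)
                                sprintf("`%s`:`%s`", p[1], p[2]),
                                character(1))))
  X <- stats::model.matrix(fml, data = d)
  list(X = X, colnames = colnames(X))
}

# Canonical design column names for a given interaction spec (levels are
# fixed, so names are data-independent).
design_colnames <- function(spec = interaction_spec(),
                            include_log_duration = FALSE) {
  lv <- feature_levels()
  row <- data.frame(age_cat = lv$age_cat[1], sex = "F",
                    edss_cat = lv$edss_cat[1],
                    relapse_distance_cat = lv$relapse_distance_cat[1],
                    relapse_count_prev_year = 0, onset_distance = 1,
                    dmt_count_cat = lv$dmt_count_cat[1],
                    current_therapy = NO_DMT, current_duration = 1,
                    index_therapy = DMT6[1], second_line_prior = FALSE,
                    log_duration = 0, stringsAsFactors = FALSE)
  build_design_matrix(row, spec, include_log_duration)$colnames
}
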