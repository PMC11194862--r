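# Effectiveness outcomes measured during the index therapy cycle:
# number of on-therapy relapses and confirmed disability progression (CDP).

#' Count relapses during a therapy cycle
#'
#' Counts relapse dates in the half-open interval `[start, end)`: a relapse on
#' the start date is on-therapy, one on the end date is not.
#'
#' @param start,end Cycle start and end dates.
#' @param relapse_dates Dates of relapse onsets for the patient.
#' @return Non-negative integer count.
#' @export
count_on_therapy_relapses <- function(start, end, relapse_dates) {
  start <- as_date(start); end <- as_date(end)
  stopifnot(length(start) == 1, length(end) == 1, start < end)
  r <- as_date(relapse_dates)
  sum(r >= start & r < end)
}

#' Baseline EDSS
#'
#' The most recent EDSS measurement dated on or before baseline (unlimited
#' lookback by default; `max_lookback_days` restricts the window).
#'
#' @param visit_dates,edss EDSS measurement dates and values.
#' @param baseline Baseline date (index therapy start).
#' @param max_lookback_days Optional maximum age, in days, of the baseline
#'   measurement.
#' @return EDSS value, or `NA` if no qualifying measurement exists.
#' @export
baseline_edss <- function(visit_dates, edss, baseline,
                          max_lookback_days = Inf) {
  d <- as.numeric(as_date(visit_dates))
  b <- as.numeric(as_date(baseline))
  keep <- !is.na(d) & !is.na(edss) & d <= b & (b - d) <= max_lookback_days
  if (!any(keep)) return(NA_real_)
  d <- d[keep]; e <- edss[keep]
  e[order(d, seq_along(d))][sum(keep)]  # latest; ties -> last recorded
}

#' Detect confirmed disability progression (CDP) during a therapy cycle
#'
#' CDP is an EDSS increase of at least 1.0 point (0.5 if baseline EDSS is
#' above 5.5) during therapy, sustained by no decrease for the following
#' 3 months and confirmed by the next EDSS measurement taken between 3 months
#' after the increase and up to 12 months after the end of the therapy. The
#' confirmatory measurement must itself reach the progression threshold and
#' be at least 3 months after any relapse. Cycles with no baseline or no
#' on-therapy EDSS measurement are classified CDP-free.
#'
#' Time conventions: 3 months = 91.3125 days, 12 months = 365.25 days.
#' "Sustained" is checked against the progression threshold by default
#' (`sustain = "threshold"`: no measurement below the threshold within
#' 3 months of the candidate); `sustain = "candidate"` instead requires no
#' measurement below the candidate's own value.
#'
#' @param start,end Cycle start and end dates.
#' @param visit_dates,edss EDSS measurement dates and values (any order;
#'   sorted internally).
#' @param relapse_dates Relapse dates for the patient.
#' @param sustain Sustainment rule, `"threshold"` (default) or `"candidate"`.
#' @return List with `cdp` (logical) and `detail` (`NULL`, or a list with
#'   `baseline_edss`, `threshold`, `candidate_date`, `confirmation_date` for
#'   the first qualifying pair).
#' @export
detect_cdp <- function(start, end, visit_dates, edss, relapse_dates,
                       sustain = c("threshold", "candidate")) {
  sustain <- match.arg(sustain)
  s <- as.numeric(as_date(start)); e <- as.numeric(as_date(end))
  stopifnot(length(s) == 1, length(e) == 1, s < e)
  vd <- as.numeric(as_date(visit_dates)); ve <- as.numeric(edss)
  keep <- !is.na(vd) & !is.na(ve)
  vd <- vd[keep]; ve <- ve[keep]
  ord <- order(vd, seq_along(vd))
  vd <- vd[ord]; ve <- ve[ord]
  rd <- as.numeric(as_date(relapse_dates)); rd <- rd[!is.na(rd)]

  no_cdp <- list(cdp = FALSE, detail = NULL)
  b <- baseline_edss(as.Date(vd, origin = "1970-01-01"), ve,
                     as.Date(s, origin = "1970-01-01"))
  if (is.na(b)) return(no_cdp)
  on_therapy <- vd > s & vd <= e
  if (!any(on_therapy)) return(no_cdp)
  thr <- if (b <= 5.5) b + 1.0 else b + 0.5

  cand <- which(on_therapy & ve >= thr)
  for (i in cand) {
    cd <- vd[i]
    ref <- if (sustain == "threshold") thr else ve[i]
    in_sustain <- vd > cd & vd <= cd + DAYS_3_MONTHS
    if (any(ve[in_sustain] < ref)) next
    nxt <- which(vd > cd + DAYS_3_MONTHS)
    if (!length(nxt)) next
    j <- nxt[1]  # "the next EDSS measurement"
    if (vd[j] > e + DAYS_12_MONTHS) next
    if (ve[j] < thr) next
    if (any(rd <= vd[j] & rd > vd[j] - DAYS_3_MONTHS)) next
    return(list(cdp = TRUE,
                detail = list(baseline_edss = b, threshold = thr,
                              candidate_date = as.Date(cd, origin = "1970-01-01"),
                              confirmation_date = as.Date(vd[j], origin = "1970-01-01"))))
  }
  no_cdp
}

#' Derive both outcomes for a set of switch pairs
#'
#' @param pairs Switch-pair table (index cycle columns `index_start`,
#'   `index_end`).
#' @param bundle Registry bundle with `visits` and `relapses`.
#' @param sustain Passed to [detect_cdp()].
#' @return Data frame with `patient_id`, `relapse_count`, `cdp`,
#'   `duration_years` and the CDP detail columns (NA when no CDP).
#' @export
derive_outcomes <- function(pairs, bundle, sustain = "threshold") {
  visits_by  <- split(bundle$visits, bundle$visits$patient_id)
  relapse_by <- split(bundle$relapses, bundle$relapses$patient_id)
  n <- nrow(pairs)
  out <- data.frame(patient_id = pairs$patient_id,
                    relapse_count = NA_integer_, cdp = NA,
                    duration_years = NA_real_,
                    cdp_baseline_edss = NA_real_, cdp_threshold = NA_real_,
                    cdp_candidate_date = as.Date(NA),
                    cdp_confirmation_date = as.Date(NA),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pid <- pairs$patient_id[i]
    s <- as_date(pairs$index_start[i]); e <- as_date(pairs$index_end[i])
    v <- visits_by[[pid]]
    r <- relapse_by[[pid]]
    rdates <- if (is.null(r)) as.Date(character(0)) else as_date(r$date)
    out$relapse_count[i] <- count_on_therapy_relapses(s, e, rdates)
    res <- detect_cdp(s, e,
                      if (is.null(v)) as.Date(character(0)) else as_date(v$date),
                      if (is.null(v)) numeric(0) else v$edss,
                      rdates, sustain = sustain)
    out$cdp[i] <- res$cdp
    if (res$cdp) {
      out$cdp_baseline_edss[i] <- res$detail$baseline_edss
      out$cdp_threshold[i] <- res$detail$threshold
      out$cdp_candidate_date[i] <- res$detail$candidate_date
      out$cdp_confirmation_date[i] <- res$detail$confirmation_date
    }
    out$duration_years[i] <- years_between(s, e)
  }
  out
}
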