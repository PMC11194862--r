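# Therapy timelines: turn raw therapy episodes into a partition of each
# patient's observed span into therapy cycles (named DMT, NoDMT gap, or
# OtherDMT overlap), then filter, censor, pair, select and split.

OPEN_END_SENTINEL <- as.Date("2262-04-11")

flowlog_new <- function() {
  data.frame(filter_name = character(0), n_before = integer(0),
             n_after = integer(0), n_removed = integer(0),
             stringsAsFactors = FALSE)
}

flowlog_add <- function(log, name, n_before, n_after) {
  stopifnot(n_after <= n_before, n_after >= 0)
  rbind(log, data.frame(filter_name = name, n_before = n_before,
                        n_after = n_after, n_removed = n_before - n_after,
                        stringsAsFactors = FALSE))
}

#' Build the therapy-cycle timeline for one patient
#'
#' Partitions the span from the first episode start to the last episode end
#' into cycles: intervals covered by exactly one DMT keep its label,
#' intervals where two or more episodes overlap become a single `OtherDMT`
#' cycle, and every between-therapy gap becomes a `NoDMT` cycle. Contiguous
#' same-DMT stretches separated by at most `merge_gap_days` are merged
#' (tolerance for registry date granularity). Episodes with a missing start
#' or an end on/before the start are not silently fixed: they are passed
#' through with a `flag` so that [quality_filter()] can remove and log them.
#'
#' @param episodes Data frame with `dmt_name`, `start_date`, `end_date`
#'   (`NA` end = ongoing episode) for a single patient.
#' @param merge_gap_days Maximum gap, in days, merged between same-DMT
#'   episodes.
#' @return Data frame of cycles: `dmt`, `start_date`, `end_date` (`NA` for an
#'   ongoing final cycle), `censored` (all `FALSE` here), `flag` (`"ok"`,
#'   `"missing_dates"` or `"invalid_interval"`).
#' @export
build_timeline <- function(episodes, merge_gap_days = 1) {
  empty <- data.frame(dmt = character(0), start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)), censored = logical(0),
                      flag = character(0), stringsAsFactors = FALSE)
  if (nrow(episodes) == 0) return(empty)
  s <- as_date(episodes$start_date)
  e <- as_date(episodes$end_date)
  flag <- rep("ok", nrow(episodes))
  flag[!is.na(s) & !is.na(e) & e <= s] <- "invalid_interval"
  flag[is.na(s)] <- "missing_dates"
  bad <- flag != "ok"
  rejected <- data.frame(dmt = as.character(episodes$dmt_name[bad]),
                         start_date = s[bad], end_date = e[bad],
                         censored = rep(FALSE, sum(bad)), flag = flag[bad],
                         stringsAsFactors = FALSE)
  s <- s[!bad]; e <- e[!bad]
  dmt <- as.character(episodes$dmt_name[!bad])
  if (length(s) == 0) return(rbind(empty, rejected))
  e_eff <- as.numeric(e)
  e_eff[is.na(e_eff)] <- as.numeric(OPEN_END_SENTINEL)
  s_num <- as.numeric(s)

  pts <- sort(unique(c(s_num, e_eff)))
  seg_start <- pts[-length(pts)]
  seg_end <- pts[-1]
  lab <- character(length(seg_start))
  for (k in seq_along(seg_start)) {
    active <- which(s_num <= seg_start[k] & e_eff >= seg_end[k])
    lab[k] <- if (length(active) == 0) NO_DMT
    else if (length(active) == 1) dmt[active]
    else OTHER_DMT
  }

  # merge adjacent segments with the same label (run-length encoding)
  first <- which(c(TRUE, lab[-1] != lab[-length(lab)]))
  last <- c(first[-1] - 1, length(lab))
  cyc <- data.frame(dmt = lab[first],
                    start = seg_start[first],
                    end = seg_end[last],
                    stringsAsFactors = FALSE)

  # absorb gaps <= merge_gap_days between two cycles of the same DMT
  repeat {
    i <- which(cyc$dmt == NO_DMT &
               (cyc$end - cyc$start) <= merge_gap_days &
               seq_len(nrow(cyc)) > 1 & seq_len(nrow(cyc)) < nrow(cyc))
    i <- i[cyc$dmt[i - 1] == cyc$dmt[i + 1]]
    if (!length(i)) break
    i <- i[1]
    cyc$end[i - 1] <- cyc$end[i + 1]
    cyc <- cyc[-c(i, i + 1), , drop = FALSE]
  }

  end_date <- as.Date(cyc$end, origin = "1970-01-01")
  end_date[cyc$end >= as.numeric(OPEN_END_SENTINEL)] <- NA
  out <- data.frame(dmt = cyc$dmt,
                    start_date = as.Date(cyc$start, origin = "1970-01-01"),
                    end_date = end_date, censored = FALSE, flag = "ok",
                    stringsAsFactors = FALSE)
  rbind(out, rejected)
}

#' Build timelines for all patients in a therapy table
#'
#' @param therapies Data frame with `patient_id`, `dmt_name`, `start_date`,
#'   `end_date`.
#' @param merge_gap_days Passed to [build_timeline()].
#' @return Cycle table with `patient_id` prepended.
#' @export
build_timelines <- function(therapies, merge_gap_days = 1) {
  pieces <- lapply(split(therapies, therapies$patient_id), function(ep) {
    cyc <- build_timeline(ep, merge_gap_days)
    if (nrow(cyc)) cyc$patient_id <- ep$patient_id[1]
    cyc
  })
  pieces <- pieces[vapply(pieces, nrow, integer(1)) > 0]
  if (!length(pieces))
    return(data.frame(patient_id = character(0), dmt = character(0),
                      start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)),
                      censored = logical(0), flag = character(0)))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[, c("patient_id", "dmt", "start_date", "end_date", "censored", "flag")]
}

#' Prepend the treatment-naive period as a NoDMT cycle
#'
#' Patients switching onto their first DMT have no preceding therapy cycle;
#' their pre-treatment disease course is represented as a NoDMT cycle from
#' disease onset to the first episode start, so that first-DMT starts form
#' valid switch pairs with current therapy NoDMT (this is also what makes
#' very long "current therapy durations" possible in the reference
#' case mix).
#'
#' @param cycles Cycle table from [build_timelines()].
#' @param patients Patient table (for `onset_date`).
#' @return Cycle table with one leading NoDMT cycle added per patient whose
#'   onset precedes the first cycle start.
#' @export
add_onset_gap <- function(cycles, patients) {
  if (nrow(cycles) == 0) return(cycles)
  first_start <- tapply(as.numeric(as_date(cycles$start_date)),
                        cycles$patient_id, min)
  pid <- names(first_start)
  onset <- as.numeric(as_date(
    patients$onset_date[match(pid, patients$patient_id)]))
  ok <- !is.na(onset) & onset < first_start
  if (!any(ok)) return(cycles)
  lead <- data.frame(patient_id = pid[ok], dmt = NO_DMT,
                     start_date = as.Date(onset[ok], origin = "1970-01-01"),
                     end_date = as.Date(first_start[ok],
                                        origin = "1970-01-01"),
                     censored = FALSE, flag = "ok",
                     stringsAsFactors = FALSE)
  out <- rbind(cycles, lead[, names(cycles)])
  out <- out[order(out$patient_id, as_date(out$start_date)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quality filter for therapy cycles
#'
#' Removes cycles with missing or invalid dates, unknown DMT labels, or a
#' start before the patient's recorded disease onset. Filters never throw on
#' content; every removal is logged under a named rule.
#'
#' @param cycles Cycle table from [build_timelines()].
#' @param patients Patient table (for `onset_date`).
#' @param known_dmts Character vector of recognized DMT labels (defaults to
#'   the six modelled DMTs plus the second-line set, `NoDMT` and `OtherDMT`).
#' @return List with filtered `cycles` and a `flowlog` data frame.
#' @export
quality_filter <- function(cycles, patients,
                           known_dmts = c(DMT6, SECOND_LINE_DMTS,
                                          NO_DMT, OTHER_DMT)) {
  log <- flowlog_new()
  drop_rule <- function(cycles, keep, rule) {
    log <<- flowlog_add(log, rule, nrow(cycles), sum(keep))
    cycles[keep, , drop = FALSE]
  }
  flag <- if ("flag" %in% names(cycles)) cycles$flag else "ok"
  cycles <- drop_rule(cycles, flag != "missing_dates" &
                        !is.na(cycles$start_date), "missing_dates")
  flag <- if ("flag" %in% names(cycles)) cycles$flag else "ok"
  ok_int <- flag != "invalid_interval" &
    (is.na(cycles$end_date) | cycles$end_date > cycles$start_date)
  cycles <- drop_rule(cycles, ok_int, "invalid_interval")
  cycles <- drop_rule(cycles, as.character(cycles$dmt) %in% known_dmts,
                      "unknown_dmt")
  onset <- as_date(patients$onset_date[match(cycles$patient_id,
                                             patients$patient_id)])
  cycles <- drop_rule(cycles, is.na(onset) |
                        as_date(cycles$start_date) >= onset,
                      "start_before_onset")
  rownames(cycles) <- NULL
  list(cycles = cycles, flowlog = log)
}

#' Form current/index switch pairs from consecutive cycles
#'
#' Every cycle with an immediate predecessor within a patient's timeline
#' yields one pair: the predecessor is the current therapy, the cycle itself
#' the (candidate) index therapy. Eligibility rules are applied separately by
#' [eligibility_filter()].
#'
#' @param cycles Cycle table (post quality filter).
#' @return Data frame with one row per pair.
#' @export
make_switch_pairs <- function(cycles) {
  pieces <- lapply(split(cycles, cycles$patient_id), function(cy) {
    cy <- cy[order(as_date(cy$start_date)), , drop = FALSE]
    if (nrow(cy) < 2) return(NULL)
    i <- 2:nrow(cy)
    data.frame(patient_id = cy$patient_id[1],
               current_dmt = cy$dmt[i - 1],
               current_start = as_date(cy$start_date[i - 1]),
               current_end = as_date(cy$end_date[i - 1]),
               index_dmt = cy$dmt[i],
               index_start = as_date(cy$start_date[i]),
               index_end = as_date(cy$end_date[i]),
               index_censored = cy$censored[i],
               stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces))
    return(data.frame(patient_id = character(0), current_dmt = character(0),
                      current_start = as.Date(character(0)),
                      current_end = as.Date(character(0)),
                      index_dmt = character(0),
                      index_start = as.Date(character(0)),
                      index_end = as.Date(character(0)),
                      index_censored = logical(0)))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Eligibility filter for switch pairs
#'
#' Keeps pairs whose index DMT is one of the six modelled DMTs, for adult
#' (age >= 18 at index start) patients with a relapsing-remitting course,
#' with the index start on or after the registry foundation and at least
#' 6 months after diagnosis. Pairs with missing birth, diagnosis or course
#' information are removed under `complete_case`.
#'
#' @param pairs Switch pairs from [make_switch_pairs()].
#' @param patients Patient table.
#' @param registry_start Registry foundation date (index cycles starting
#'   earlier are removed).
#' @return List with filtered `pairs` and a `flowlog`.
#' @export
eligibility_filter <- function(pairs, patients,
                               registry_start = as.Date("2011-01-01")) {
  registry_start <- as_date(registry_start)
  log <- flowlog_new()
  drop_rule <- function(pairs, keep, rule) {
    log <<- flowlog_add(log, rule, nrow(pairs), sum(keep))
    pairs[keep, , drop = FALSE]
  }
  idx <- function() match(pairs$patient_id, patients$patient_id)

  pairs <- drop_rule(pairs, pairs$index_dmt %in% DMT6, "index_not_6dmt")
  p <- patients[idx(), , drop = FALSE]
  complete <- !is.na(p$birth_date) & !is.na(p$diagnosis_date) &
    !is.na(p$course_label)
  pairs <- drop_rule(pairs, complete, "complete_case")
  p <- patients[idx(), , drop = FALSE]
  age <- years_between(as_date(p$birth_date), as_date(pairs$index_start))
  pairs <- drop_rule(pairs, age >= 18, "age_under_18")
  p <- patients[idx(), , drop = FALSE]
  pairs <- drop_rule(pairs, as_date(pairs$index_start) >= registry_start,
                     "before_registry_start")
  p <- patients[idx(), , drop = FALSE]
  min_start <- as.Date(as.numeric(as_date(p$diagnosis_date)) + DAYS_6_MONTHS,
                       origin = "1970-01-01")
  pairs <- drop_rule(pairs, as_date(pairs$index_start) >= min_start,
                     "min_6_months_post_diagnosis")
  p <- patients[idx(), , drop = FALSE]
  pairs <- drop_rule(pairs, p$course_label == "RRMS", "not_rrms")
  rownames(pairs) <- NULL
  list(pairs = pairs, flowlog = log)
}

#' Censor cycles at the last EDSS measurement before a cutoff
#'
#' Any cycle whose end is open (`NA`) or on/after `cutoff_date` has its end
#' replaced by the date of that patient's last EDSS measurement strictly
#' before the cutoff and is marked censored. Cycles with no qualifying EDSS
#' measurement after their start are dropped (zero follow-up) and logged.
#'
#' @param cycles Data frame with `patient_id`, `start_date`, `end_date`,
#'   `censored` columns (switch pairs can be censored on their index cycle
#'   via `start_col`/`end_col`).
#' @param visits EDSS visit table (`patient_id`, `date`).
#' @param cutoff_date Censoring cutoff.
#' @param start_col,end_col,censored_col Column names to operate on.
#' @return List with `cycles` and a `flowlog` (rule
#'   `"no_edss_before_cutoff"`).
#' @export
censor_at_last_edss <- function(cycles, visits, cutoff_date,
                                start_col = "start_date",
                                end_col = "end_date",
                                censored_col = "censored") {
  cutoff <- as.numeric(as_date(cutoff_date))
  vdate <- as.numeric(as_date(visits$date))
  keep_v <- !is.na(vdate) & vdate < cutoff
  last_edss <- tapply(vdate[keep_v], visits$patient_id[keep_v], max)

  end <- as.numeric(as_date(cycles[[end_col]]))
  start <- as.numeric(as_date(cycles[[start_col]]))
  needs <- is.na(end) | end >= cutoff
  new_end <- end
  cens <- if (censored_col %in% names(cycles)) cycles[[censored_col]] else
    rep(FALSE, nrow(cycles))
  le <- as.numeric(last_edss[cycles$patient_id])
  new_end[needs] <- le[needs]
  cens[needs] <- TRUE
  ok <- !is.na(new_end) & new_end > start
  log <- flowlog_add(flowlog_new(), "no_edss_before_cutoff",
                     nrow(cycles), sum(ok))
  cycles[[end_col]] <- as.Date(new_end, origin = "1970-01-01")
  cycles[[censored_col]] <- cens
  cycles <- cycles[ok, , drop = FALSE]
  rownames(cycles) <- NULL
  list(cycles = cycles, flowlog = log)
}

#' Select one switch pair per patient, uniformly at random
#'
#' @param pairs Switch-pair table.
#' @param seed Integer seed; the selection is deterministic given the seed
#'   and independent of input row order.
#' @return One row per patient.
#' @export
select_one_cycle_per_patient <- function(pairs, seed = 1L) {
  if (nrow(pairs) == 0) return(pairs)
  ord <- order(pairs$patient_id, as_date(pairs$index_start),
               pairs$index_dmt)
  pairs <- pairs[ord, , drop = FALSE]
  picked <- with_local_seed(seed, {
    vapply(split(seq_len(nrow(pairs)), pairs$patient_id), function(rows) {
      if (length(rows) == 1) rows else rows[sample.int(length(rows), 1)]
    }, integer(1))
  })
  out <- pairs[sort(unname(picked)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Temporal train/test split on the index therapy start date
#'
#' Pairs with an index start strictly before `split_date` form the training
#' set; pairs starting on or after it form the test set.
#'
#' @param pairs Switch-pair table (one per patient).
#' @param split_date Split date (default the main-analysis 2017-01-01; the
#'   sensitivity analysis uses 2019-07-01).
#' @return List with `train` and `test`.
#' @export
temporal_split <- function(pairs, split_date = as.Date("2017-01-01")) {
  split_date <- as_date(split_date)
  is_train <- as_date(pairs$index_start) < split_date
  list(train = pairs[is_train, , drop = FALSE],
       test = pairs[!is_train, , drop = FALSE])
}
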