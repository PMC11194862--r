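# Raw longitudinal registry generation (second simulator tier) and
# registry-bundle file I/O.

# Catalogue of planted EDSS trajectories around a therapy episode [S, E].
# Each entry returns visit (date, edss) and relapse-date vectors plus the
# expected verdict of the progression detector. Near-misses violate exactly
# one condition: sustainment, confirmation window, or relapse adjacency.
plant_trajectory <- function(type, S, E, b) {
  thr <- if (b <= 5.5) b + 1.0 else b + 0.5
  S <- as.numeric(S); E <- as.numeric(E)
  cd <- S + 100
  base <- list(dates = c(S - 20, S + 30), edss = c(b, b))
  relapses <- numeric(0)
  if (type == "planted_positive") {
    dates <- c(base$dates, cd, cd + 120, cd + 220)
    edss <- c(base$edss, thr, thr, thr)
  } else if (type == "nearmiss_sustain") {
    # dip below threshold 50 days after the increase
    dates <- c(base$dates, cd, cd + 50, cd + 120)
    edss <- c(base$edss, thr, thr - 0.5, thr - 0.5)
  } else if (type == "nearmiss_window") {
    # next measurement after the increase falls beyond end + 12 months
    c2 <- E - 30
    dates <- c(base$dates, c2, E + DAYS_12_MONTHS + 40)
    edss <- c(base$edss, thr, thr)
  } else if (type == "nearmiss_relapse") {
    # relapse 45 days before the confirmatory measurement
    dates <- c(base$dates, cd, cd + 120)
    edss <- c(base$edss, thr, thr)
    relapses <- cd + 75
  } else stop("unknown plant type: ", type)
  list(dates = as.Date(round(dates), origin = "1970-01-01"),
       edss = edss,
       relapses = as.Date(round(relapses), origin = "1970-01-01"),
       expected_cdp = type == "planted_positive")
}

PLANT_TYPES <- c("planted_positive", "nearmiss_sustain",
                 "nearmiss_window", "nearmiss_relapse")

#' Generate a raw registry bundle
#'
#' Emits four linked longitudinal tables (patients, EDSS visits, relapse
#' events, therapy episodes) with configurable gap/overlap/open-end rates,
#' EDSS measured in 0.5 steps at jittered visit intervals, and relapse
#' events from a gamma-mixed Poisson process with centre effects (so window
#' counts are negative-binomial). A `cdp_plant_rate` fraction of patients
#' receive a constructed trajectory from the progression catalogue
#' (positives, plus near-misses violating exactly one detection condition);
#' their expected verdicts are returned in `truth_cdp`.
#'
#' @param config A [sim_config()].
#' @return List of class `registry_bundle`: `patients`, `visits`,
#'   `relapses`, `therapies`, `truth_cdp`, `config`.
#' @export
generate_raw_registry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$visit_interval_days[["mean"]] <= 0)
    stop("visit_interval_days must be positive", call. = FALSE)
  win0 <- as.numeric(config$study_window[1])
  win1 <- as.numeric(config$study_window[2])
  if (win1 <= win0) stop("empty study window", call. = FALSE)
  n <- config$n_patients
  empty <- structure(list(
    patients = data.frame(patient_id = character(0), centre_id = integer(0),
                          sex = character(0),
                          birth_date = as.Date(character(0)),
                          onset_date = as.Date(character(0)),
                          diagnosis_date = as.Date(character(0)),
                          course_label = character(0)),
    visits = data.frame(patient_id = character(0),
                        date = as.Date(character(0)), edss = numeric(0)),
    relapses = data.frame(patient_id = character(0),
                          date = as.Date(character(0))),
    therapies = data.frame(patient_id = character(0), dmt_name = character(0),
                           start_date = as.Date(character(0)),
                           end_date = as.Date(character(0))),
    truth_cdp = data.frame(patient_id = character(0), dmt = character(0),
                           start_date = as.Date(character(0)),
                           end_date = as.Date(character(0)),
                           type = character(0), expected_cdp = logical(0)),
    config = config), class = "registry_bundle")
  if (n == 0) return(empty)

  with_local_seed(config$seed + 1L, {
    cm <- config$case_mix
    dd <- config$duration_dist
    u_centre <- stats::rnorm(config$n_centres, 0, config$sigma_centre)
    n_plant <- round(config$cdp_plant_rate * n)
    plant_ids <- if (n_plant > 0) sample.int(n, n_plant) else integer(0)
    plant_type <- stats::setNames(
      PLANT_TYPES[(seq_len(n_plant) - 1L) %% length(PLANT_TYPES) + 1L],
      plant_ids)

    pat <- list(); vis <- list(); rel <- list(); ther <- list(); tru <- list()
    other_named <- c("rituximab", "ocrelizumab")
    for (i in seq_len(n)) {
      pid <- sprintf("P%05d", i)
      centre <- sample.int(config$n_centres, 1)
      sex <- if (stats::runif(1) < cm$sex_f) "F" else "M"
      planted <- i %in% plant_ids
      age0 <- stats::runif(1, 20, 55)           # age at window start
      birth <- win0 - age0 * DAYS_PER_YEAR
      # planted trajectories need room for a confirmation window before the
      # extraction date, so their disease history starts early in the window
      onset <- win0 + stats::runif(1, -10, if (planted) 0.5 else 4) *
        DAYS_PER_YEAR
      onset <- max(onset, birth + 15 * DAYS_PER_YEAR)
      diagnosis <- onset + stats::runif(1, 30, 700)
      course <- if (stats::runif(1) < config$nonrrms_rate) "SPMS" else "RRMS"

      starts <- ends <- numeric(0); dmts <- character(0)
      if (planted) {
        t0 <- max(win0, diagnosis) + stats::runif(1, 250, 600)
        d1 <- stats::runif(1, 200, 500)
        gap <- stats::runif(1, 40, 300)
        d2 <- stats::runif(1, 600, 900)
        a <- sample(DMT6, 2)
        starts <- c(t0, t0 + d1 + gap)
        ends <- c(t0 + d1, t0 + d1 + gap + d2)
        dmts <- a
        need <- ends[2] + DAYS_12_MONTHS + 60 - win1
        if (need > 0) {
          shift <- min(need, starts[1] - (max(win0, diagnosis) + 10))
          if (shift > 0) { starts <- starts - shift; ends <- ends - shift }
        }
      } else {
        t <- max(win0, diagnosis) + stats::runif(1, 60, 1200)
        k <- 1 + stats::rpois(1, 1.8)
        for (j in seq_len(k)) {
          if (t >= win1 - 30) break
          dmt <- if (stats::runif(1) < 0.05) sample(other_named, 1)
                 else sample(names(cm$index_therapy), 1,
                             prob = cm$index_therapy)
          dur <- stats::rlnorm(1, dd$index[["meanlog"]],
                               dd$index[["sdlog"]]) * DAYS_PER_YEAR
          dur <- min(max(dur, 30), 8 * DAYS_PER_YEAR)
          starts <- c(starts, t); ends <- c(ends, t + dur)
          dmts <- c(dmts, dmt)
          if (stats::runif(1) < config$overlap_rate) {
            t <- t + dur - stats::runif(1, 20, min(200, dur - 10))
          } else if (stats::runif(1) < config$gap_rate) {
            t <- t + dur + stats::runif(1, 20, 600)
          } else {
            t <- t + dur   # direct switch: cycles abut exactly
          }
        }
      }
      if (!length(starts)) next
      open <- rep(FALSE, length(ends))
      if (!planted) {
        over <- which(ends > win1)
        last <- length(ends)
        if (length(over)) {
          ends[setdiff(over, last)] <- win1   # clamp non-final overruns
          if (last %in% over) open[last] <- TRUE
        } else if (stats::runif(1) < config$open_end_rate) open[last] <- TRUE
      }
      end_dates <- as.Date(round(ends), origin = "1970-01-01")
      end_dates[open] <- NA
      ther[[length(ther) + 1L]] <- data.frame(
        patient_id = pid, dmt_name = dmts,
        start_date = as.Date(round(starts), origin = "1970-01-01"),
        end_date = end_dates, stringsAsFactors = FALSE)

      if (planted) {
        b <- if (length(tru) %% 2 == 0) 2.0 else 6.0
        tr <- plant_trajectory(plant_type[[as.character(i)]],
                               starts[2], ends[2], b)
        vis[[length(vis) + 1L]] <- data.frame(
          patient_id = pid, date = tr$dates, edss = tr$edss,
          stringsAsFactors = FALSE)
        if (length(tr$relapses))
          rel[[length(rel) + 1L]] <- data.frame(
            patient_id = pid, date = tr$relapses, stringsAsFactors = FALSE)
        tru[[length(tru) + 1L]] <- data.frame(
          patient_id = pid, dmt = dmts[2],
          start_date = as.Date(round(starts[2]), origin = "1970-01-01"),
          end_date = as.Date(round(ends[2]), origin = "1970-01-01"),
          type = plant_type[[as.character(i)]],
          expected_cdp = tr$expected_cdp, stringsAsFactors = FALSE)
      } else {
        vstart <- max(win0, min(starts) - stats::runif(1, 30, 400))
        last_end <- max(ifelse(open, win1, ends))
        vend <- min(win1, last_end + stats::runif(1, 0, 300))
        iv <- config$visit_interval_days
        t <- vstart; dates <- numeric(0)
        while (t <= vend) {
          dates <- c(dates, t)
          t <- t + max(14, stats::rnorm(1, iv[["mean"]], iv[["jitter"]]))
        }
        if (length(dates)) {
          e0 <- sample(seq(0, 6, by = 0.5), 1,
                       prob = stats::dexp(seq(0, 6, by = 0.5), 0.5))
          steps <- sample(c(-0.5, 0, 0.5), length(dates) - 1, replace = TRUE,
                          prob = c(0.12, 0.70, 0.18))
          edss <- pmin(10, pmax(0, e0 + cumsum(c(0, steps))))
          vis[[length(vis) + 1L]] <- data.frame(
            patient_id = pid, date = as.Date(round(dates),
                                             origin = "1970-01-01"),
            edss = edss, stringsAsFactors = FALSE)
        }
        rate <- config$relapse_rate * exp(u_centre[centre]) *
          stats::rgamma(1, shape = config$phi, rate = config$phi)
        span_years <- (vend - vstart) / DAYS_PER_YEAR
        n_rel <- stats::rpois(1, rate * span_years)
        if (n_rel > 0)
          rel[[length(rel) + 1L]] <- data.frame(
            patient_id = pid,
            date = as.Date(round(stats::runif(n_rel, vstart, vend)),
                           origin = "1970-01-01"),
            stringsAsFactors = FALSE)
      }
      pat[[length(pat) + 1L]] <- data.frame(
        patient_id = pid, centre_id = centre, sex = sex,
        birth_date = as.Date(round(birth), origin = "1970-01-01"),
        onset_date = as.Date(round(onset), origin = "1970-01-01"),
        diagnosis_date = as.Date(round(diagnosis), origin = "1970-01-01"),
        course_label = course, stringsAsFactors = FALSE)
    }
    bind <- function(lst, proto) {
      if (!length(lst)) return(proto)
      out <- do.call(rbind, lst); rownames(out) <- NULL; out
    }
    structure(list(patients = bind(pat, empty$patients),
                   visits = bind(vis, empty$visits),
                   relapses = bind(rel, empty$relapses),
                   therapies = bind(ther, empty$therapies),
                   truth_cdp = bind(tru, empty$truth_cdp),
                   config = config),
              class = "registry_bundle")
  })
}

#' Write / read a registry bundle as four CSV files
#'
#' Dates are written in ISO-8601; the simulation truth (config and planted
#' trajectory labels) is written to a JSON sidecar.
#'
#' @param bundle A `registry_bundle`.
#' @param dir Directory (created if needed).
#' @return `write_registry` returns `dir` invisibly; `read_registry`
#'   returns a `registry_bundle` (without config).
#' @export
write_registry <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "visits", "relapses", "therapies"))
    utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  truth <- list(truth_cdp = bundle$truth_cdp,
                config = unclass(bundle$config))
  truth$config$study_window <- format(bundle$config$study_window)
  truth$config$interaction_spec <- unclass(bundle$config$interaction_spec)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       Date = "ISO8601")
  invisible(dir)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  rd <- function(nm, date_cols) {
    x <- utils::read.csv(file.path(dir, paste0(nm, ".csv")),
                         stringsAsFactors = FALSE)
    for (dc in intersect(date_cols, names(x))) x[[dc]] <- as.Date(x[[dc]])
    x
  }
  structure(list(
    patients = rd("patients", c("birth_date", "onset_date", "diagnosis_date")),
    visits = rd("visits", "date"),
    relapses = rd("relapses", "date"),
    therapies = rd("therapies", c("start_date", "end_date")),
    truth_cdp = NULL, config = NULL), class = "registry_bundle")
}
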