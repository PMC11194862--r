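# Small registry fixtures built in code.

d <- function(x) as.Date(x)

# One-patient bundle with fully controllable tables.
mini_bundle <- function(patients = NULL, visits = NULL, relapses = NULL,
                        therapies = NULL) {
  list(
    patients = patients %||% data.frame(
      patient_id = "P1", centre_id = 1L, sex = "F",
      birth_date = d("1980-06-15"), onset_date = d("2008-03-01"),
      diagnosis_date = d("2008-09-01"), course_label = "RRMS",
      stringsAsFactors = FALSE),
    visits = visits %||% data.frame(
      patient_id = character(0), date = d(character(0)), edss = numeric(0)),
    relapses = relapses %||% data.frame(
      patient_id = character(0), date = d(character(0))),
    therapies = therapies %||% data.frame(
      patient_id = character(0), dmt_name = character(0),
      start_date = d(character(0)), end_date = d(character(0))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

episodes <- function(...) {
  rows <- list(...)
  data.frame(
    dmt_name = vapply(rows, `[[`, "", 1),
    start_date = d(vapply(rows, `[[`, "", 2)),
    end_date = d(vapply(rows, function(r)
      if (length(r) < 3 || is.na(r[3])) NA_character_ else r[3], "")),
    stringsAsFactors = FALSE)
}

# A small, fast simulation config for model tests.
quick_config <- function(..., seed = 1) {
  sim_config(n_patients = 500, n_centres = 10, seed = seed, ...)
}

# Flat config: all slopes zero, no centre variation, unit duration.
flat_config <- function(b0 = log(0.3), p0 = 0.1, phi = 1, seed = 1) {
  br <- default_true_coefs("relapse"); br[] <- 0
  br["(Intercept)"] <- b0
  bc <- default_true_coefs("cdp"); bc[] <- 0
  bc["(Intercept)"] <- qlogis(p0)
  dd <- default_duration_dist()
  dd$index <- c(meanlog = 0, sdlog = 0)      # duration exactly 1 year
  sim_config(sigma_centre = 0, phi = phi, beta_relapse = br, beta_cdp = bc,
             duration_dist = dd, seed = seed)
}
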