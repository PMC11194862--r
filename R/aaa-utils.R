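# Shared constants and small helpers.

# The six disease-modifying treatments (DMTs) modelled as index therapies.
DMT6 <- c("dimethyl fumarate", "fingolimod", "glatiramer acetate",
          "interferon beta1", "natalizumab", "teriflunomide")

# Second-line DMTs: prior exposure to any of these sets the second-line flag.
SECOND_LINE_DMTS <- c("alemtuzumab", "cyclophosphamide", "fingolimod",
                      "mitoxantrone", "natalizumab", "ocrelizumab",
                      "rituximab")

NO_DMT    <- "NoDMT"    # no-therapy gap in a treatment timeline
OTHER_DMT <- "OtherDMT" # interval where two or more DMTs overlap

# Date arithmetic: internal unit is days.
DAYS_PER_YEAR   <- 365.25
DAYS_PER_MONTH  <- 30.4375
DAYS_3_MONTHS   <- 3 * DAYS_PER_MONTH   # 91.3125
DAYS_6_MONTHS   <- 6 * DAYS_PER_MONTH
DAYS_12_MONTHS  <- DAYS_PER_YEAR

#' Names of the six modelled disease-modifying treatments
#'
#' @return Character vector of the six DMT labels usable as index therapy.
#' @export
dmt_names <- function() DMT6

#' Names of the second-line disease-modifying treatments
#'
#' @return Character vector of DMT labels counted as second-line exposure.
#' @export
second_line_dmts <- function() SECOND_LINE_DMTS

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date <- function(x) {
  if (inherits(x, "Date")) x else as.Date(x)
}

years_between <- function(from, to) {
  as.numeric(to - from) / DAYS_PER_YEAR
}

stopifnot_scalar_date <- function(x, name) {
  if (length(x) != 1L || is.na(as_date(x)))
    stop(sprintf("'%s' must be a single valid date", name), call. = FALSE)
}

# Evaluate `expr` with a private RNG stream, restoring the caller's stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
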