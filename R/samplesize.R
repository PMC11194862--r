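# Sample size for testing a C-index against a null value.

auc_variance <- function(auc, n_events, n_nonevents,
                         method = c("hanley", "noether")) {
  method <- match.arg(method)
  if (method == "hanley") {
    # Hanley & McNeil (1982) variance of the empirical AUC
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    (auc * (1 - auc) + (n_events - 1) * (q1 - auc^2) +
       (n_nonevents - 1) * (q2 - auc^2)) / (n_events * n_nonevents)
  } else {
    # Noether: Mann-Whitney null-style variance
    (n_events + n_nonevents + 1) / (12 * n_events * n_nonevents)
  }
}

#' Power of a two-sided C-index test at a given total sample size
#'
#' Normal-approximation power for testing `H0: C = c_null` against the
#' alternative `c_alt`, with the event fraction fixed at `prevalence`
#' (`n_events = prevalence * N`). The null variance is evaluated at
#' `c_null`, the alternative variance at `c_alt`.
#'
#' @param n Total sample size.
#' @param c_null,c_alt Null and alternative C-index, both in (0.5, 1).
#' @param alpha Two-sided significance level.
#' @param prevalence Event fraction in (0, 1).
#' @param method Variance formula: `"hanley"` (default) or `"noether"`.
#' @return Power in (0, 1).
#' @export
cindex_power <- function(n, c_null, c_alt, alpha = 0.05, prevalence = 0.25,
                         method = "hanley") {
  n1 <- prevalence * n
  n0 <- (1 - prevalence) * n
  se0 <- sqrt(auc_variance(c_null, n1, n0, method))
  se1 <- sqrt(auc_variance(c_alt, n1, n0, method))
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm((abs(c_alt - c_null) - z * se0) / se1)
}

#' Sample size for a C-index test
#'
#' Smallest total `N` for which a two-sided level-`alpha` test of the null
#' C-index attains the target power at the alternative, under the declared
#' variance formula with the event fraction fixed at the prevalence. The
#' returned `N` brackets the target: power at `N` reaches it, power at
#' `N - 1` does not.
#'
#' @param c_null,c_alt Null and alternative C-index, in (0.5, 1), unequal.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @param prevalence Event fraction.
#' @param method Variance formula (`"hanley"` or `"noether"`).
#' @return Integer total sample size.
#' @export
cindex_sample_size <- function(c_null = 0.6, c_alt = 0.65, alpha = 0.05,
                               power = 0.9, prevalence = 0.25,
                               method = "hanley") {
  stopifnot(c_null > 0.5, c_null < 1, c_alt > 0.5, c_alt < 1,
            alpha > 0, alpha < 1, power > 0, power < 1,
            prevalence > 0, prevalence < 1)
  if (c_alt == c_null)
    stop("c_alt equals c_null: no finite sample size attains the power",
         call. = FALSE)
  n <- 8L  # need at least a couple of events
  while (cindex_power(n, c_null, c_alt, alpha, prevalence, method) < power) {
    n <- n + 1L
    if (n > 10000000L)
      stop("sample size search did not terminate", call. = FALSE)
  }
  n
}
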