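# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles (double loops, pair enumeration) and share
# no code with the package implementations they check.

M3 <- 3 * 30.4375
M12 <- 365.25

# Progression oracle: enumerate every (candidate, confirmation) measurement
# pair and re-check all conditions independently.
oracle_cdp <- function(start, end, visit_dates, edss, relapse_dates) {
  s <- as.numeric(as.Date(start)); e <- as.numeric(as.Date(end))
  vd <- as.numeric(as.Date(visit_dates)); ve <- as.numeric(edss)
  ok <- !is.na(vd) & !is.na(ve)
  vd <- vd[ok]; ve <- ve[ok]
  o <- order(vd, seq_along(vd)); vd <- vd[o]; ve <- ve[o]
  rd <- as.numeric(as.Date(relapse_dates))

  pre <- which(vd <= s)
  if (length(pre) == 0) return(FALSE)
  b <- ve[pre[length(pre)]]
  thr <- if (b > 5.5) b + 0.5 else b + 1.0
  if (!any(vd > s & vd <= e)) return(FALSE)

  for (i in seq_along(vd)) {
    # condition 1: candidate is an on-therapy measurement at/above threshold
    if (!(vd[i] > s && vd[i] <= e)) next
    if (ve[i] < thr) next
    # condition 2: sustained - nothing below threshold within 3 months
    sustained <- TRUE
    for (k in seq_along(vd))
      if (vd[k] > vd[i] && vd[k] <= vd[i] + M3 && ve[k] < thr)
        sustained <- FALSE
    if (!sustained) next
    for (j in seq_along(vd)) {
      # condition 3: confirmation is the next measurement 3+ months later
      if (!(vd[j] > vd[i] + M3)) next
      is_next <- TRUE
      for (k in seq_along(vd))
        if (vd[k] > vd[i] + M3 && (vd[k] < vd[j] || (vd[k] == vd[j] && k < j)))
          is_next <- FALSE
      if (!is_next) next
      # condition 4: within 12 months of therapy end, at/above threshold
      if (vd[j] > e + M12) next
      if (ve[j] < thr) next
      # condition 5: at least 3 months after any relapse
      near_relapse <- FALSE
      for (r in rd) if (r <= vd[j] && r > vd[j] - M3) near_relapse <- TRUE
      if (near_relapse) next
      return(TRUE)
    }
  }
  FALSE
}

# Random EDSS trajectory around a therapy cycle, dense in edge cases.
random_trajectory <- function() {
  end <- runif(1, 120, 900)
  nv <- rpois(1, 8) + 1
  dates <- sort(round(runif(nv, -400, end + 500)))
  if (runif(1) < 0.5) {
    edss <- sample(seq(0, 10, 0.5), nv, replace = TRUE,
                   prob = dexp(seq(0, 10, 0.5), 0.35))
  } else {
    e0 <- sample(seq(0, 7, 0.5), 1)
    edss <- pmin(10, pmax(0, e0 + cumsum(sample(c(-0.5, 0, 0.5, 1), nv,
                                                TRUE, c(.2, .35, .3, .15)))))
  }
  nr <- rpois(1, 1.5)
  relapses <- round(runif(nr, -200, end + 400))
  list(start = as.Date("2015-01-01"),
       end = as.Date("2015-01-01") + end,
       visit_dates = as.Date("2015-01-01") + dates,
       edss = edss,
       relapse_dates = as.Date("2015-01-01") + relapses)
}

# O(n^2) concordance: all pairs with unequal outcomes, ties in the
# prediction score one half.
oracle_c_index <- function(pred, obs) {
  conc <- 0; comp <- 0
  n <- length(obs)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (obs[i] == obs[j]) next
    comp <- comp + 1
    hi <- if (obs[i] > obs[j]) i else j
    lo <- if (obs[i] > obs[j]) j else i
    if (pred[hi] > pred[lo]) conc <- conc + 1
    else if (pred[hi] == pred[lo]) conc <- conc + 0.5
  }
  conc / comp
}

oracle_mse <- function(pred, obs) {
  tot <- 0
  for (i in seq_along(obs)) tot <- tot + (pred[i] - obs[i])^2
  tot / length(obs)
}

# Spearman via explicit mid-ranking and the Pearson formula.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v))
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Negative-binomial zero probability through the pmf, not the closed form.
oracle_nb_zero <- function(mu, phi) dnbinom(0, size = phi, mu = mu)

# Power oracle for the C-index sample size: its own Hanley-McNeil variance
# code plus a grid search over N.
oracle_cindex_power <- function(N, c0, c1, alpha, prev) {
  hm_var <- function(A, m, n) {
    (A * (1 - A) + (m - 1) * (A / (2 - A) - A^2) +
       (n - 1) * (2 * A^2 / (1 + A) - A^2)) / (m * n)
  }
  m <- prev * N; n <- (1 - prev) * N
  crit <- qnorm(1 - alpha / 2) * sqrt(hm_var(c0, m, n))
  pnorm(((c1 - c0) - crit) / sqrt(hm_var(c1, m, n)))
}

oracle_cindex_n <- function(c0, c1, alpha, power, prev, n_max = 20000) {
  for (N in 4:n_max)
    if (oracle_cindex_power(N, c0, c1, alpha, prev) >= power) return(N)
  stop("oracle grid search exhausted")
}
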