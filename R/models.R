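# Outcome models: hierarchical GLMMs with centre random intercepts and their
# fixed-effects counterparts, plus per-DMT counterfactual prediction with a
# null (average) centre effect.
#
# The hierarchical fit uses a Laplace approximation (lme4) and represents
# posterior uncertainty by Gaussian draws around the mode: coefficient draws
# from MVN(hat(beta), vcov), dispersion draws lognormal via the delta method,
# centre-intercept draws from their conditional means and SDs. With the
# weakly-informative priors of the replicated strategy and the sample sizes
# involved, this normal approximation is the standard large-sample stand-in
# for full MCMC (no sampler backend is assumed to be available).

#' Model specification
#'
#' @param family `"negbinomial"` (relapse counts, log link, log-duration
#'   offset) or `"binomial"` (CDP occurrence, logit link).
#' @param interaction_spec An [interaction_spec()].
#' @param n_draws Number of posterior draws to generate.
#' @param seed Seed for the draw generator.
#' @param nAGQ Laplace/AGQ setting passed to lme4 (0 = fastest, the default
#'   reduced preset; 1 = standard Laplace).
#' @param prior_scale Retained for interface compatibility; the Gaussian
#'   approximation treats weakly-informative priors as locally uniform.
#' @param max_rhat,min_ess,max_divergences Convergence thresholds applied to
#'   the draw diagnostics. The Gaussian-approximation backend produces
#'   independent draws, so these are guard rails against numerical
#'   pathologies rather than mixing checks; the effective ESS floor is
#'   capped at half the draw count so reduced presets stay usable.
#' @param theta_iter Number of dispersion re-estimation sweeps for the
#'   negative-binomial GLMM.
#' @param cdp_log_duration Include log index duration as a fixed effect in
#'   the binomial model (the CDP model has no offset; follow-up enters as a
#'   covariate). Set `FALSE` to exclude follow-up adjustment.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family = c("negbinomial", "binomial"),
                       interaction_spec = dmtresponse::interaction_spec(),
                       n_draws = 2000L, seed = 1L, nAGQ = 0L,
                       prior_scale = 2.5, max_rhat = 1.05, min_ess = 400,
                       max_divergences = 0L, theta_iter = 2L,
                       cdp_log_duration = TRUE) {
  family <- match.arg(family)
  stopifnot(inherits(interaction_spec, "interaction_spec"),
            n_draws >= 2, max_rhat > 1, min_ess > 0)
  structure(list(family = family, interaction_spec = interaction_spec,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 nAGQ = as.integer(nAGQ), prior_scale = prior_scale,
                 max_rhat = max_rhat, min_ess = min_ess,
                 max_divergences = as.integer(max_divergences),
                 theta_iter = as.integer(theta_iter),
                 cdp_log_duration = cdp_log_duration),
            class = "model_spec")
}

spec_outcome <- function(spec, data) {
  if (spec$family == "negbinomial") as.numeric(data$relapse_count)
  else as.integer(data$cdp)
}

spec_includes_logdur <- function(spec) {
  spec$family == "binomial" && isTRUE(spec$cdp_log_duration)
}

model_design <- function(data, spec, standardization = NULL) {
  if (!is.null(standardization))
    data <- apply_standardization(standardization, data)
  dm <- build_design_matrix(data, spec$interaction_spec,
                            include_log_duration = spec_includes_logdur(spec))
  X <- dm$X
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient (", ncol(X), " columns, rank ",
         qr(X)$rank, ")", call. = FALSE)
  X
}

# split-chain R-hat and a crude autocorrelation ESS for a draw vector
draw_rhat <- function(x, n_chains = 4L) {
  n <- floor(length(x) / n_chains) * n_chains
  m <- matrix(x[seq_len(n)], ncol = n_chains)
  cm <- colMeans(m); w <- mean(apply(m, 2, stats::var))
  b <- nrow(m) * stats::var(cm)
  if (w <= 0) return(1)
  sqrt(((nrow(m) - 1) / nrow(m) * w + b / nrow(m)) / w)
}

draw_ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  a <- stats::acf(x, lag.max = min(100, n - 1), plot = FALSE)$acf[-1]
  pos <- which(a < 0.05)
  k <- if (length(pos)) pos[1] - 1 else length(a)
  max(1, n / (1 + 2 * sum(a[seq_len(k)])))
}

check_convergence <- function(draws_beta, spec) {
  rhat <- apply(draws_beta, 2, draw_rhat)
  ess <- apply(draws_beta, 2, draw_ess)
  diag <- data.frame(parameter = colnames(draws_beta), rhat = rhat,
                     ess = ess, divergences = 0L, row.names = NULL)
  ess_floor <- min(spec$min_ess, nrow(draws_beta) / 2)
  bad <- diag$parameter[diag$rhat > spec$max_rhat | diag$ess < ess_floor]
  if (length(bad))
    stop("convergence thresholds breached for parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  diag
}

safe_names <- function(p) sprintf("x%03d", seq_len(p))

#' Fit the hierarchical model with a centre random intercept
#'
#' @param data Analysis rows: complete feature columns plus `centre_id`,
#'   the outcome column (`relapse_count` or `cdp`) and
#'   `duration_years`/`log_duration`.
#' @param spec A [model_spec()].
#' @param standardization Optional [fit_standardization()] parameters,
#'   applied before building the design and stored with the fit.
#' @return Object of class `posterior_fit` with coefficient/dispersion/
#'   centre-intercept draws, point estimates, diagnostics, and everything
#'   needed to predict on new rows.
#' @export
fit_hierarchical <- function(data, spec, standardization = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  X <- model_design(data, spec, standardization)
  y <- spec_outcome(spec, data)
  centre <- factor(data$centre_id)
  off <- if (spec$family == "negbinomial") data$log_duration else NULL

  p <- ncol(X)
  nm <- safe_names(p)
  d <- as.data.frame(X); names(d) <- nm
  d$.y <- y; d$.centre <- centre
  fml <- stats::as.formula(paste(".y ~ 0 +", paste(nm, collapse = " + "),
                                 "+ (1 | .centre)"))
  theta <- NULL; theta_se_log <- NULL
  ctrl <- lme4::glmerControl(check.conv.singular = "ignore",
                             calc.derivs = FALSE)
  if (spec$family == "negbinomial") {
    # moment/ML dispersion from a fast Poisson fit, then iterate
    init <- stats::glm.fit(X, y, offset = off, family = stats::poisson())
    th <- MASS::theta.ml(y, init$fitted.values, limit = 50)
    for (it in seq_len(max(1L, spec$theta_iter))) {
      fit <- lme4::glmer(fml, data = d, offset = off,
                         family = MASS::negative.binomial(theta = th[[1]]),
                         nAGQ = spec$nAGQ, control = ctrl)
      th_new <- MASS::theta.ml(y, stats::fitted(fit), limit = 50)
      done <- abs(th_new[[1]] - th[[1]]) / th[[1]] < 0.02
      th <- th_new
      if (done) break
    }
    theta <- th[[1]]
    theta_se_log <- attr(th, "SE") / theta
  } else {
    fit <- lme4::glmer(fml, data = d, family = stats::binomial(),
                       nAGQ = spec$nAGQ, control = ctrl)
  }
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0)
    stop("optimizer failed to converge (code ", fit@optinfo$conv$opt, "): ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "),
         call. = FALSE)

  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  sigma_c <- sqrt(unname(unlist(lme4::VarCorr(fit)))[1])
  re <- lme4::ranef(fit, condVar = TRUE)$.centre
  u_mode <- stats::setNames(re[["(Intercept)"]], rownames(re))
  u_sd <- sqrt(drop(attr(re, "postVar")))

  nd <- spec$n_draws
  draws <- with_local_seed(spec$seed, {
    b <- MASS::mvrnorm(nd, mu = beta, Sigma = V)
    colnames(b) <- colnames(X)
    phi <- if (spec$family == "negbinomial")
      exp(stats::rnorm(nd, log(theta), theta_se_log)) else NULL
    u <- vapply(seq_along(u_mode),
                function(g) stats::rnorm(nd, u_mode[g], u_sd[g]),
                numeric(nd))
    colnames(u) <- names(u_mode)
    # variance-component profile uncertainty is not propagated by the
    # Gaussian approximation; sigma draws are held at the Laplace estimate
    list(beta = b, phi = phi, sigma_centre = rep(sigma_c, nd), u = u)
  })
  diag <- check_convergence(draws$beta, spec)

  structure(list(engine = "laplace_gaussian", family = spec$family,
                 spec = spec, standardization = standardization,
                 coef = stats::setNames(as.numeric(beta), colnames(X)),
                 vcov = `dimnames<-`(V, list(colnames(X), colnames(X))),
                 theta = theta, theta_se_log = theta_se_log,
                 sigma_centre = sigma_c,
                 u_mode = u_mode, u_sd = u_sd,
                 draws = draws, diagnostics = diag,
                 n_obs = nrow(X)),
            class = "posterior_fit")
}

#' Fit the non-hierarchical fixed-effects GLM
#'
#' Maximum-likelihood fit with the centre effect excluded from the design;
#' for the negative binomial the dispersion is estimated jointly.
#'
#' @inheritParams fit_hierarchical
#' @return Object of class `glm_fit`.
#' @export
fit_glm_fixed <- function(data, spec, standardization = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  X <- model_design(data, spec, standardization)
  y <- spec_outcome(spec, data)
  p <- ncol(X); nm <- safe_names(p)
  d <- as.data.frame(X); names(d) <- nm
  d$.y <- y
  if (spec$family == "negbinomial") {
    d$.off <- data$log_duration
    fml <- stats::as.formula(paste(".y ~ 0 +", paste(nm, collapse = " + "),
                                   "+ offset(.off)"))
    fit <- MASS::glm.nb(fml, data = d)
    theta <- fit$theta; theta_se <- fit$SE.theta
  } else {
    fml <- stats::as.formula(paste(".y ~ 0 +", paste(nm, collapse = " + ")))
    fit <- stats::glm(fml, data = d, family = stats::binomial())
    theta <- NULL; theta_se <- NULL
  }
  if (!fit$converged)
    stop("GLM failed to converge after ", fit$iter,
         " IWLS iterations (possible separation); deviance trace ends at ",
         format(fit$deviance), call. = FALSE)
  co <- stats::setNames(stats::coef(fit), colnames(X))
  V <- `dimnames<-`(as.matrix(stats::vcov(fit)),
                    list(colnames(X), colnames(X)))
  structure(list(engine = "ml_fixed", family = spec$family, spec = spec,
                 standardization = standardization,
                 coef = co, vcov = V, theta = theta, theta_se = theta_se,
                 loglik = as.numeric(stats::logLik(fit)),
                 iterations = fit$iter, n_obs = nrow(X)),
            class = "glm_fit")
}

prepare_prediction_rows <- function(fit, rows, index_dmt, duration) {
  if (!is.null(index_dmt)) {
    if (!index_dmt %in% DMT6) stop("unknown DMT: ", index_dmt, call. = FALSE)
    rows$index_therapy <- factor(index_dmt, levels = INDEX_THERAPY_LEVELS)
  }
  if (!is.null(duration)) {
    if (any(duration <= 0)) stop("duration must be positive", call. = FALSE)
    rows$duration_years <- duration
    rows$log_duration <- log(duration)
  }
  if (is.null(rows$duration_years) || any(rows$duration_years <= 0))
    stop("rows need a positive duration (duration_years)", call. = FALSE)
  if (!is.null(fit$standardization))
    rows <- apply_standardization(fit$standardization, rows)
  X <- build_design_matrix(rows, fit$spec$interaction_spec,
                           include_log_duration =
                             spec_includes_logdur(fit$spec))$X
  list(X = X, log_d = log(rows$duration_years))
}

nb_prob_zero <- function(mu, phi) (phi / (phi + mu))^phi

#' Predict outcomes for feature rows under a given index DMT
#'
#' Sets the index therapy and follow-up duration, assumes an average centre
#' effect (null random intercept), and summarizes the predictions: per row
#' the predicted mean outcome (expected relapse count, or CDP probability),
#' the outcome-free probability (negative-binomial `P(count = 0)`, or
#' `1 - p`), and a central 95% interval of the mean.
#'
#' @param fit A `posterior_fit` or `glm_fit`.
#' @param rows Complete feature rows (unstandardized; the fit's stored
#'   train-set standardization is applied internally).
#' @param index_dmt One of the six DMT labels, or `NULL` to keep each row's
#'   own index therapy.
#' @param duration Follow-up duration in years (scalar or per-row), or
#'   `NULL` to keep each row's own duration.
#' @param ... Unused.
#' @return Data frame with `mean`, `outcome_free`, `lower`, `upper`.
#' @export
predict_outcomes <- function(fit, rows, index_dmt = NULL, duration = NULL,
                             ...) {
  UseMethod("predict_outcomes")
}

#' @export
predict_outcomes.posterior_fit <- function(fit, rows, index_dmt = NULL,
                                           duration = NULL, ...) {
  pr <- prepare_prediction_rows(fit, rows, index_dmt, duration)
  eta <- pr$X %*% t(fit$draws$beta)              # n x n_draws
  if (fit$family == "negbinomial") {
    mu <- exp(eta + pr$log_d)
    free <- sweep_nb_zero(mu, fit$draws$phi)
    val <- mu
  } else {
    val <- stats::plogis(eta)
    free <- 1 - val
  }
  qs <- t(apply(val, 1, stats::quantile, probs = c(0.025, 0.975),
                names = FALSE))
  data.frame(mean = rowMeans(val), outcome_free = rowMeans(free),
             lower = qs[, 1], upper = qs[, 2])
}

sweep_nb_zero <- function(mu, phi) {
  # P(count = 0) per draw, phi varying over columns
  t(nb_prob_zero(t(mu), phi))
}

#' @export
predict_outcomes.glm_fit <- function(fit, rows, index_dmt = NULL,
                                     duration = NULL, ...) {
  pr <- prepare_prediction_rows(fit, rows, index_dmt, duration)
  X <- pr$X
  eta <- drop(X %*% fit$coef)
  se <- sqrt(rowSums((X %*% fit$vcov) * X))
  if (fit$family == "negbinomial") {
    mu <- exp(eta + pr$log_d)
    data.frame(mean = mu, outcome_free = nb_prob_zero(mu, fit$theta),
               lower = exp(eta - 1.96 * se + pr$log_d),
               upper = exp(eta + 1.96 * se + pr$log_d))
  } else {
    p <- stats::plogis(eta)
    data.frame(mean = p, outcome_free = 1 - p,
               lower = stats::plogis(eta - 1.96 * se),
               upper = stats::plogis(eta + 1.96 * se))
  }
}

#' Predict outcomes under each of the six DMTs
#'
#' Applies [predict_outcomes()] for every index DMT with otherwise identical
#' covariates, and ranks the DMTs per row by outcome-free probability
#' (rank 1 = highest probability of staying outcome-free).
#'
#' @inheritParams predict_outcomes
#' @return Long data frame: `row`, `index_dmt`, `mean`, `outcome_free`,
#'   `lower`, `upper`, `rank` (six rows per input row).
#' @export
predict_all_dmts <- function(fit, rows, duration = NULL) {
  out <- do.call(rbind, lapply(DMT6, function(dmt) {
    p <- predict_outcomes(fit, rows, index_dmt = dmt, duration = duration)
    cbind(data.frame(row = seq_len(nrow(p)), index_dmt = dmt,
                     stringsAsFactors = FALSE), p)
  }))
  out$rank <- stats::ave(-out$outcome_free, out$row,
                         FUN = function(z) rank(z, ties.method = "first"))
  out <- out[order(out$row, out$rank), ]
  rownames(out) <- NULL
  out
}

#' Median absolute deviations of the posterior coefficient draws
#'
#' Used to compare coefficient precision across models. Scaled by 1.4826
#' (consistent for a normal distribution) by default; `constant = 1` gives
#' the raw MAD.
#'
#' @param fit A `posterior_fit`.
#' @param constant Scale factor passed to [stats::mad()].
#' @return Named numeric vector, one MAD per coefficient.
#' @export
coefficient_mads <- function(fit, constant = 1.4826) {
  stopifnot(inherits(fit, "posterior_fit"))
  apply(fit$draws$beta, 2, stats::mad, constant = constant)
}

#' Save / load a fitted model
#'
#' Round-trips a fit so that reloaded objects reproduce identical
#' predictions.
#'
#' @param fit A fit object.
#' @param path File path.
#' @export
save_fit <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_fit
#' @export
load_fit <- function(path) readRDS(path)
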