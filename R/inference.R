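validate_observation_table <- function(table) {
  if (!is.data.frame(table)) stop("`table` must be a data.frame", call. = FALSE)
  needed <- c("unit_id", "obs_id", "duration", "count")
  miss <- setdiff(needed, names(table))
  if (length(miss)) {
    stop("observation table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(table$count) ||
      any(!is.finite(table$count)) ||
      any(table$count < 0) ||
      any(abs(table$count - round(table$count)) > 1e-8)) {
    stop(paste("`count` must hold non-negative integers: the raw number of",
               "observed events must be modelled, never a pre-divided rate",
               "(use the log-duration offset for varying exposure)"),
         call. = FALSE)
  }
  if (!is.numeric(table$duration) || any(!is.finite(table$duration)) ||
      any(table$duration <= 0)) {
    stop("`duration` must be positive (hours)", call. = FALSE)
  }
  invisible(table)
}

#' Fit a Poisson-lognormal GLMM to an observation table
#'
#' Fits `count ~ fixed + (1 | unit_id) + (1 | obs_id)` with Poisson errors, a
#' log link, and `log(duration)` as an offset (a covariate with slope fixed
#' to 1, the exposure model). The observation-level random effect (OLRE)
#' absorbs overdispersion beyond the Poisson, so the stochastic counting
#' error is modelled explicitly and the two latent variances — between-unit
#' `var_between` and observation-level `var_olre` — estimate the biological
#' variance components free of it. Counts are used raw: tables whose `count`
#' column is not integral are rejected.
#'
#' @param table observation table (data.frame with `unit_id`, `obs_id`,
#'   `duration`, `count`, plus any covariates).
#' @param fixed character vector of covariate names to include as fixed
#'   effects (default none: intercept only).
#' @param family `"poisson"` (Poisson-lognormal with OLRE, the default) or
#'   `"nbinom"` (negative-binomial alternative, Poisson-gamma overdispersion
#'   instead of the OLRE; needs the glmmTMB package).
#' @param min_units,min_obs_per_unit below these the variances are poorly
#'   identified and a warning is raised.
#' @return Object of class `count_glmm`: list with `intercept_latent`
#'   (log events/hour), `var_between`, `var_olre`, `fixed_effects`
#'   (matrix of estimate/SE), `offset_used`, `fit_method`, `converged`,
#'   `n_units`, `n_obs`, and the underlying fitted `model`.
#' @examples
#' \donttest{
#' tab <- simulate_study(10, 0.3, 0.5, n_units = 50, obs_per_unit = 4,
#'                       duration = 2, seed = 1)
#' fit <- fit_count_glmm(tab)
#' icc_report(fit, reference_duration = 2)
#' }
#' @export
fit_count_glmm <- function(table, fixed = NULL,
                           family = c("poisson", "nbinom"),
                           min_units = 20L, min_obs_per_unit = 2L) {
  validate_observation_table(table)
  family <- match.arg(family)
  miss <- setdiff(fixed, names(table))
  if (length(miss)) {
    stop("fixed-effect columns not in table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab <- table
  tab$unit_id <- factor(tab$unit_id)
  tab$.olre <- factor(seq_len(nrow(tab)))
  n_units <- nlevels(tab$unit_id)
  obs_per_unit <- nrow(tab) / n_units
  if (n_units < min_units || obs_per_unit < min_obs_per_unit) {
    warning(sprintf(
      "only %d units with %.1f observations each on average; variance components will be imprecise",
      n_units, obs_per_unit), call. = FALSE)
  }
  rhs <- paste(c("1", fixed, "(1 | unit_id)"), collapse = " + ")
  if (family == "poisson") {
    form <- stats::as.formula(paste("count ~", rhs, "+ (1 | .olre)"))
    model <- lme4::glmer(form, data = tab, family = stats::poisson(),
                         offset = log(tab$duration),
                         control = lme4::glmerControl(calc.derivs = FALSE))
    vc <- lme4::VarCorr(model)
    var_between <- as.numeric(vc$unit_id)
    var_olre <- as.numeric(vc$.olre)
    beta <- lme4::fixef(model)
    se <- sqrt(diag(as.matrix(stats::vcov(model))))
    conv <- length(model@optinfo$conv$lme4$messages) == 0
    method <- "lme4::glmer Laplace (Poisson-lognormal, OLRE)"
  } else {
    if (!requireNamespace("glmmTMB", quietly = TRUE)) {
      stop("the nbinom backend needs the glmmTMB package", call. = FALSE)
    }
    form <- stats::as.formula(paste("count ~", rhs))
    model <- glmmTMB::glmmTMB(form, data = tab,
                              family = glmmTMB::nbinom2(),
                              offset = log(tab$duration))
    vc <- glmmTMB::VarCorr(model)$cond
    var_between <- as.numeric(vc$unit_id)
    var_olre <- NA_real_  # overdispersion held by the NB dispersion instead
    beta <- glmmTMB::fixef(model)$cond
    se <- sqrt(diag(as.matrix(stats::vcov(model)$cond)))
    conv <- isTRUE(model$fit$convergence == 0)
    method <- "glmmTMB nbinom2 (Poisson-gamma)"
  }
  structure(
    list(intercept_latent = unname(beta[["(Intercept)"]]),
         var_between = var_between,
         var_olre = var_olre,
         fixed_effects = cbind(estimate = beta, se = se),
         offset_used = TRUE,
         fit_method = method,
         family = family,
         converged = conv,
         n_units = n_units, n_obs = nrow(tab),
         model = model),
    class = "count_glmm"
  )
}

#' @export
print.count_glmm <- function(x, ...) {
  cat("Count GLMM (", x$fit_method, ")\n", sep = "")
  cat(sprintf("  %d observations of %d units; log-duration offset\n",
              x$n_obs, x$n_units))
  cat(sprintf("  latent intercept (log events/hour): %.4g\n",
              x$intercept_latent))
  cat(sprintf("  var between units (latent): %.4g\n", x$var_between))
  cat(sprintf("  var observation-level (latent): %.4g\n", x$var_olre))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' ICC / repeatability on latent, expected and observed scales
#'
#' Converts the latent variance components of a Poisson-lognormal GLMM into
#' the three ICC variants:
#' * `icc_latent = s2B / (s2B + s2E)`: ratio of latent (log-scale) variances.
#' * `icc_expected`: the arithmetic expected-rate scale,
#'   `(exp(s2B) - 1) / (exp(s2B + s2E) - 1)` — stochastic error excluded;
#'   this is the biologically meaningful repeatability, independent of
#'   sampling effort.
#' * `icc_observed`: latent-scale ratio with the Poisson
#'   distribution-specific variance added to the denominator via the
#'   lognormal-Poisson approximation `ln(1 + 1/m)`, where
#'   `m = exp(intercept + (s2B + s2E)/2) * reference_duration` is the mean
#'   count at the chosen observation length. This reproduces what a naive
#'   observed-scale analysis can recover and depends on `reference_duration`.
#'
#' Also reports `cv_b`, the coefficient of between-unit variation: the SD of
#' unit effects on the latent scale, comparable across studies regardless of
#' sampling effort.
#'
#' @param fit a converged [fit_count_glmm()] result (Poisson family).
#' @param reference_duration observation period (hours) at which the
#'   observed-scale ICC is evaluated.
#' @return Object of class `icc_report`: list with `icc_latent`,
#'   `icc_expected`, `icc_observed`, `cv_b`, `mean_count_reference`,
#'   `scale_notes`.
#' @export
icc_report <- function(fit, reference_duration = 1) {
  stopifnot(inherits(fit, "count_glmm"))
  if (!identical(fit$family, "poisson")) {
    stop("icc_report needs the Poisson-lognormal fit", call. = FALSE)
  }
  if (!fit$converged) {
    stop("fit did not converge; refusing to derive ICCs from it",
         call. = FALSE)
  }
  stopifnot(reference_duration > 0)
  s2b <- fit$var_between
  s2e <- fit$var_olre
  tot <- s2b + s2e
  m_ref <- exp(fit$intercept_latent + tot / 2) * reference_duration
  var_dist <- log1p(1 / m_ref)
  structure(
    list(icc_latent = if (tot > 0) s2b / tot else 1,
         icc_expected = if (tot > 0) expm1(s2b) / expm1(tot) else 1,
         icc_observed = s2b / (tot + var_dist),
         cv_b = sqrt(s2b),
         mean_count_reference = m_ref,
         reference_duration = reference_duration,
         scale_notes = paste("observed scale adds lognormal-Poisson",
                             "distribution-specific variance ln(1 + 1/m)",
                             "at the reference duration")),
    class = "icc_report"
  )
}

#' @export
print.icc_report <- function(x, ...) {
  cat("Repeatability (ICC) report\n")
  cat(sprintf("  latent scale   : %.4g\n", x$icc_latent))
  cat(sprintf("  expected scale : %.4g  (stochastic error excluded)\n",
              x$icc_expected))
  cat(sprintf("  observed scale : %.4g  (at %.3g h, mean count %.3g)\n",
              x$icc_observed, x$reference_duration, x$mean_count_reference))
  cat(sprintf("  CV_B (latent-scale between-unit SD): %.4g\n", x$cv_b))
  invisible(x)
}

#' Naive Gaussian mixed model on counts or rates (biased comparator)
#'
#' Fits `response ~ 1 + (1 | unit_id)` with Gaussian errors, where the
#' response is the raw count or the rate `count / duration`. This is the
#' analysis most published studies use; it leaves the stochastic counting
#' error in the residual, so its ICC is attenuated toward
#' [attenuate_icc()]'s prediction. Provided to demonstrate and measure that
#' bias — the output is flagged as a biased comparator.
#'
#' @param table observation table.
#' @param response `"count"` or `"rate"`.
#' @return list with `icc_observed`, `var_unit`, `var_residual`, `response`,
#'   `biased_comparator = TRUE`, `model`.
#' @export
fit_naive_lmm <- function(table, response = c("count", "rate")) {
  validate_observation_table(table)
  response <- match.arg(response)
  tab <- table
  tab$.resp <- if (response == "count") tab$count else tab$count / tab$duration
  tab$unit_id <- factor(tab$unit_id)
  model <- suppressMessages(
    lme4::lmer(.resp ~ 1 + (1 | unit_id), data = tab,
               control = lme4::lmerControl(calc.derivs = FALSE)))
  vc <- lme4::VarCorr(model)
  vu <- as.numeric(vc$unit_id)
  vr <- attr(vc, "sc")^2
  list(icc_observed = vu / (vu + vr),
       var_unit = vu, var_residual = vr,
       response = response, biased_comparator = TRUE, model = model)
}

## Marginal negative log-likelihood of the errors-in-variables model,
## integrating the latent log-rate out with Gauss-Hermite quadrature.
## theta = (mu, log sigma, a, b, log sigma_res)
eiv_negloglik <- function(theta, y, t, w, gh) {
  mu <- theta[1]; sig <- exp(theta[2])
  a <- theta[3]; b <- theta[4]; sr <- exp(theta[5])
  z <- sqrt(2) * gh$x                     # quadrature nodes for N(0,1)
  lw <- log(gh$w) - 0.5 * log(pi)
  lam <- exp(mu + sig * z)                # latent rates at the nodes
  n <- length(y)
  ll <- numeric(n)
  for (i in seq_len(n)) {
    li <- lw + dpois(y[i], lam * t[i], log = TRUE) +
      dnorm(w[i], a + b * lam, sr, log = TRUE)
    m <- max(li)
    ll[i] <- m + log(sum(exp(li - m)))
  }
  -sum(ll)
}

#' Errors-in-variables regression with a latent event rate as predictor
#'
#' Joint model for using a behavioural rate, observed only through counts,
#' as a predictor of another (Gaussian) outcome:
#' \deqn{y_i \sim Poisson(\lambda_i t_i), \quad \log\lambda_i \sim
#'   N(\mu, \sigma^2), \quad w_i \sim N(a + b\,\lambda_i, \sigma_{res})}
#' fitted by marginal maximum likelihood, integrating the latent log-rate
#' out with Gauss-Hermite quadrature. The slope `b` (outcome units per
#' event/hour) is the target: a naive regression of the outcome on the
#' observed rate `y/t` attenuates it by roughly the biological proportion of
#' observed variance, while this model does not.
#'
#' @param table observation table with an outcome column.
#' @param outcome name of the outcome column (default `"outcome"`).
#' @param nodes number of Gauss-Hermite nodes.
#' @param conf_level level for Wald intervals.
#' @return Object of class `eiv_fit`: list with `slope`, `intercept`,
#'   `resid_sd`, `latent_mu`, `latent_sigma`, `latent_rate_mean`,
#'   `latent_rate_var`, `ci` (matrix of Wald intervals), `loglik`,
#'   `converged`, `n`.
#' @export
fit_error_in_variable <- function(table, outcome = "outcome", nodes = 40,
                                  conf_level = 0.95) {
  validate_observation_table(table)
  if (!outcome %in% names(table)) {
    stop("no such outcome column: ", outcome, call. = FALSE)
  }
  w <- table[[outcome]]
  if (!is.numeric(w) || any(!is.finite(w))) {
    stop("outcome must be numeric and finite", call. = FALSE)
  }
  if (sd(w) < 1e-12) {
    stop("outcome is constant; the regression is degenerate", call. = FALSE)
  }
  y <- table$count; t <- table$duration
  if (nrow(table) < 50) {
    warning("fewer than 50 rows; errors-in-variables estimates will be noisy",
            call. = FALSE)
  }
  gh <- pracma::gaussHermite(nodes)

  # moment-based starting values
  rate <- y / t
  mhat <- mean(rate)
  cv2 <- max(1e-4, as.numeric(expected_cv(mean(y), sd(y)))^2)
  sig0 <- sqrt(log1p(cv2))
  mu0 <- log(mhat) - sig0^2 / 2
  ab <- stats::coef(stats::lm(w ~ rate))
  theta0 <- c(mu0, log(sig0), ab[1], ab[2], log(max(sd(w) / 2, 1e-3)))

  opt <- optim(theta0, eiv_negloglik, y = y, t = t, w = w, gh = gh,
               method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-10))
  th <- opt$par
  vcov_th <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, 5, 5)
  })
  se <- sqrt(pmax(diag(vcov_th), 0))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  ci <- cbind(estimate = th, lower = th - zq * se, upper = th + zq * se)
  rownames(ci) <- c("mu", "log_sigma", "intercept", "slope", "log_resid_sd")
  sig <- exp(th[2])
  structure(
    list(slope = th[4], intercept = th[3], resid_sd = exp(th[5]),
         latent_mu = th[1], latent_sigma = sig,
         latent_rate_mean = exp(th[1] + sig^2 / 2),
         latent_rate_var = expm1(sig^2) * exp(2 * th[1] + sig^2),
         ci = ci, loglik = -opt$value,
         converged = opt$convergence == 0, n = length(y)),
    class = "eiv_fit"
  )
}

#' @export
print.eiv_fit <- function(x, ...) {
  cat("Errors-in-variables fit (latent Poisson rate as predictor)\n")
  cat(sprintf("  slope: %.4g  [%.4g, %.4g]\n",
              x$slope, x$ci["slope", "lower"], x$ci["slope", "upper"]))
  cat(sprintf("  intercept: %.4g   residual SD: %.4g\n",
              x$intercept, x$resid_sd))
  cat(sprintf("  latent rate: mean %.4g events/h, CV %.3g\n",
              x$latent_rate_mean,
              sqrt(x$latent_rate_var) / x$latent_rate_mean))
  if (!x$converged) cat("  WARNING: optimiser did not report convergence\n")
  invisible(x)
}
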