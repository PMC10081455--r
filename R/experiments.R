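#' Bias/precision experiment for effect-size estimators over a sampling grid
#'
#' For every combination of mean count and expected CV, simulates replicate
#' studies with [simulate_study()] (duration 1 h, rate = mean count) and
#' estimates the effect size with the requested methods:
#' * `"naive-lmm"`: Gaussian mixed model on raw counts; ICC on the observed
#'   scale (stochastic error left in) — the biased comparator.
#' * `"poisson-glmm"`: Poisson-lognormal GLMM with OLRE; expected-scale ICC
#'   from [icc_report()] — the corrected estimator.
#' * `"naive-lm-predictor"`: ordinary regression of a simulated outcome on
#'   the observed rate; R-squared — biased comparator for the predictor case.
#' * `"eiv"`: errors-in-variables model; latent-scale R-squared — corrected
#'   estimator for the predictor case.
#' For the predictor methods an outcome is simulated per observation as
#' `w = lambda + e` with the error variance chosen so the true latent
#' R-squared equals `effect_true`.
#'
#' @param grid_mean_counts numeric vector of mean events per observation.
#' @param grid_cv_exp numeric vector of expected CVs (> 0).
#' @param effect_true true expected-scale ICC (response methods) or latent
#'   R-squared (predictor methods), in `(0, 1)`.
#' @param n_units,obs_per_unit study dimensions per replicate.
#' @param replicates simulated studies per cell (>= 10).
#' @param methods subset of
#'   `c("naive-lmm", "poisson-glmm", "naive-lm-predictor", "eiv")`.
#' @param seed integer seed; the whole experiment is reproducible from it.
#' @return data.frame of class `bias_experiment` with one row per
#'   (cell, method): `mean_count`, `cv_exp`, `method`, `estimate_mean`,
#'   `estimate_sd`, `bias`, `precision` (1/variance), `n_ok`, `n_failed`,
#'   plus attributes `effect_true` and `config`.
#' @export
run_bias_experiment <- function(grid_mean_counts, grid_cv_exp, effect_true,
                                n_units = 50, obs_per_unit = 4,
                                replicates = 20,
                                methods = c("naive-lmm", "poisson-glmm"),
                                seed = 1) {
  known <- c("naive-lmm", "poisson-glmm", "naive-lm-predictor", "eiv")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    stop("unknown method(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  stopifnot(length(grid_mean_counts) >= 1, length(grid_cv_exp) >= 1,
            replicates >= 10, effect_true > 0, effect_true < 1)
  cells <- expand.grid(mean_count = grid_mean_counts, cv_exp = grid_cv_exp,
                       KEEP.OUT.ATTRS = FALSE)
  set.seed(as.integer(seed))
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    m <- cells$mean_count[ci]; cv <- cells$cv_exp[ci]
    est <- matrix(NA_real_, nrow = replicates, ncol = length(methods),
                  dimnames = list(NULL, methods))
    for (r in seq_len(replicates)) {
      tab <- simulate_study(mean_rate = m, cv_exp = cv,
                            icc_exp = effect_true,
                            n_units = n_units, obs_per_unit = obs_per_unit,
                            duration = 1)
      if (any(c("naive-lm-predictor", "eiv") %in% methods)) {
        lam <- attr(tab, "truth")$lambda
        # error variance giving Var(lambda)/(Var(lambda)+s2) = effect_true
        s2 <- (m * cv)^2 * (1 - effect_true) / effect_true
        tab$outcome <- lam + rnorm(nrow(tab), 0, sqrt(s2))
      }
      for (meth in methods) {
        est[r, meth] <- tryCatch(
          switch(meth,
            "naive-lmm" = fit_naive_lmm(tab, "count")$icc_observed,
            "poisson-glmm" = {
              fit <- suppressWarnings(fit_count_glmm(tab))
              icc_report(fit, reference_duration = 1)$icc_expected
            },
            "naive-lm-predictor" = {
              summary(stats::lm(outcome ~ I(count / duration),
                                data = tab))$r.squared
            },
            "eiv" = {
              f <- suppressWarnings(fit_error_in_variable(tab))
              num <- f$slope^2 * f$latent_rate_var
              num / (num + f$resid_sd^2)
            }),
          error = function(e) NA_real_)
      }
    }
    for (meth in methods) {
      ok <- est[, meth][is.finite(est[, meth])]
      rows[[length(rows) + 1L]] <- data.frame(
        mean_count = m, cv_exp = cv, method = meth,
        estimate_mean = if (length(ok)) mean(ok) else NA_real_,
        estimate_sd = if (length(ok) > 1) sd(ok) else NA_real_,
        bias = if (length(ok)) mean(ok) - effect_true else NA_real_,
        precision = if (length(ok) > 1) 1 / var(ok) else NA_real_,
        n_ok = length(ok), n_failed = replicates - length(ok),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "effect_true") <- effect_true
  attr(out, "config") <- list(n_units = n_units, obs_per_unit = obs_per_unit,
                              replicates = replicates, seed = seed,
                              methods = methods)
  class(out) <- c("bias_experiment", class(out))
  out
}

#' Analytic attenuation curve for naive estimators
#'
#' The effect size a naive (Gaussian, stochastic-error-ignoring) analysis is
#' expected to report, as a function of the mean number of observed events:
#' [attenuate_icc()] evaluated along the grid. Overlay on
#' [run_bias_experiment()] output to compare simulation with theory.
#'
#' @param mean_counts numeric vector.
#' @param cv_exp expected CV.
#' @param effect_true expected-scale ICC / R-squared.
#' @param shape gamma renewal shape.
#' @return data.frame with `mean_count` and `attenuated`.
#' @export
naive_curve <- function(mean_counts, cv_exp, effect_true, shape = 1) {
  data.frame(mean_count = mean_counts,
             attenuated = attenuate_icc(effect_true, mean_counts, cv_exp,
                                        shape))
}

#' Incidence of underdispersed samples across simulated studies
#'
#' At low mean counts and low expected CV, sampling noise often makes the
#' sample variance of counts fall below the sample mean, so the expected CV
#' is unrecoverable (set to 0 by convention). This measures how often, by
#' simulating `replicates` studies per grid cell (Poisson process) and
#' recording the fraction with `var(count) < mean(count)`.
#'
#' @inheritParams run_bias_experiment
#' @param grid_cv_exp expected CVs (>= 0 here; 0 is a legitimate null cell).
#' @param n_obs observations per simulated study.
#' @return data.frame with `mean_count`, `cv_exp`, `incidence`.
#' @export
underdispersion_incidence <- function(grid_mean_counts, grid_cv_exp,
                                      n_obs = 100, replicates = 500,
                                      seed = 1) {
  stopifnot(all(grid_mean_counts > 0), all(grid_cv_exp >= 0), replicates >= 1)
  set.seed(as.integer(seed))
  cells <- expand.grid(mean_count = grid_mean_counts, cv_exp = grid_cv_exp,
                       KEEP.OUT.ATTRS = FALSE)
  cells$incidence <- NA_real_
  for (ci in seq_len(nrow(cells))) {
    m <- cells$mean_count[ci]; cv <- cells$cv_exp[ci]
    s2 <- log1p(cv^2)
    under <- logical(replicates)
    for (r in seq_len(replicates)) {
      lam <- m * exp(rnorm(n_obs, 0, sqrt(s2)) - s2 / 2)
      y <- rpois(n_obs, lam)
      under[r] <- var(y) < mean(y)
    }
    cells$incidence[ci] <- mean(under)
  }
  cells
}
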