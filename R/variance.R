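#' Decompose observed count variance into stochastic and biological parts
#'
#' By the law of total variance, the variance of observed counts across
#' observations splits as `var_observed = var_stochastic + var_expected`,
#' where the stochastic part is the counting noise of the point process
#' (`mean_count / shape`; equal to the mean for a Poisson process) and the
#' expected part is the variance of the latent expected counts,
#' `(mean_count * cv_exp)^2`.
#'
#' @param mean_count mean number of events per observation, `lambda * t`
#'   (> 0).
#' @param cv_exp coefficient of variation of expected rates (>= 0).
#' @param shape gamma renewal shape `alpha` (>= 1); the stochastic variance
#'   is `mean_count / shape`, so 1 is the Poisson case and larger values
#'   model a refractory period (underdispersion).
#' @return An object of class `variance_decomposition`: list with
#'   `mean_count`, `var_stochastic`, `var_expected`, `var_observed`,
#'   `sd_observed`, `cv_stoc`, `cv_exp`, `cv_observed`,
#'   `proportion_biological`, `shape`.
#' @examples
#' decompose_variance(20, 0.3)  # 20 +/- 7.5 events per observation
#' @export
decompose_variance <- function(mean_count, cv_exp, shape = 1) {
  stopifnot(is.numeric(mean_count), length(mean_count) == 1L, mean_count > 0,
            is.numeric(cv_exp), length(cv_exp) == 1L, cv_exp >= 0,
            is.numeric(shape), length(shape) == 1L, shape >= 1)
  var_stoc <- mean_count / shape
  var_exp <- (mean_count * cv_exp)^2
  var_obs <- var_stoc + var_exp
  structure(
    list(mean_count = mean_count,
         var_stochastic = var_stoc,
         var_expected = var_exp,
         var_observed = var_obs,
         sd_observed = sqrt(var_obs),
         cv_stoc = sqrt(var_stoc) / mean_count,
         cv_exp = cv_exp,
         cv_observed = sqrt(var_obs) / mean_count,
         proportion_biological = var_exp / var_obs,
         shape = shape),
    class = "variance_decomposition"
  )
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("Count variance decomposition (mean %.4g events, alpha = %.3g)\n",
              x$mean_count, x$shape))
  cat(sprintf("  stochastic variance : %.4g (CV %.3g)\n",
              x$var_stochastic, x$cv_stoc))
  cat(sprintf("  expected-rate variance: %.4g (CV %.3g)\n",
              x$var_expected, x$cv_exp))
  cat(sprintf("  observed: variance %.4g, SD %.4g, CV %.3g\n",
              x$var_observed, x$sd_observed, x$cv_observed))
  cat(sprintf("  proportion biological: %.4g\n", x$proportion_biological))
  invisible(x)
}

#' Expected CV of rates recovered from a count-scale mean and SD
#'
#' Inverts the variance decomposition for the Poisson case: since the
#' observed variance is `mean + (mean * cv_exp)^2`, the CV of expected rates
#' is `sqrt(sd^2 - mean) / mean`. When `sd^2 <= mean` (no overdispersion) the
#' expected CV cannot be computed; by convention it is set to 0 and flagged.
#'
#' @param mean,sd mean and standard deviation of counts *on the count scale*
#'   (events per observation). `mean` must be > 0.
#' @return numeric CV with attribute `underdispersed` (logical).
#' @examples
#' expected_cv(10, 5.4)   # 0.438
#' expected_cv(10, 3.75)  # 0.2: SD deflated by rescaling to per-hour
#' @export
expected_cv <- function(mean, sd) {
  stopifnot(is.numeric(mean), length(mean) == 1L,
            is.numeric(sd), length(sd) == 1L, sd >= 0)
  if (!is.finite(mean) || mean <= 0) {
    stop("`mean` must be a positive count-scale mean", call. = FALSE)
  }
  excess <- sd^2 - mean
  if (excess <= mean * 1e-10) {
    return(structure(0, underdispersed = TRUE))
  }
  structure(sqrt(excess) / mean, underdispersed = FALSE)
}

#' Is an expected-CV estimate flagged as underdispersed?
#' @param cv a value returned by [expected_cv()].
#' @return logical.
#' @export
is_underdispersed <- function(cv) isTRUE(attr(cv, "underdispersed"))

#' Proportion of observed count variance that is biological
#'
#' The share of observed variance due to variation in expected rates:
#' `(shape * m * cv^2) / (1 + shape * m * cv^2)` with `m = mean_count`.
#' For a Poisson process (`shape = 1`) this is `m cv^2 / (1 + m cv^2)`. It
#' is the ceiling on any variance-standardised effect size (ICC, R-squared)
#' estimated from raw counts without modelling the stochastic error, and it
#' grows monotonically with both the mean count and the expected CV.
#'
#' @inheritParams decompose_variance
#' @return proportion in `[0, 1)`. Vectorised over `mean_count` and `cv_exp`.
#' @examples
#' biological_proportion(20, 0.3)  # 9/14
#' @export
biological_proportion <- function(mean_count, cv_exp, shape = 1) {
  stopifnot(all(mean_count > 0), all(cv_exp >= 0), all(shape >= 1))
  x <- shape * mean_count * cv_exp^2
  x / (1 + x)
}

#' Attenuated (observed-scale) ICC or R-squared
#'
#' The effect size estimated from raw counts when stochastic error is left in
#' the denominator: the expected-scale value times the biological proportion
#' of observed variance. Linear in `icc_exp` and monotone increasing in
#' `mean_count` and `cv_exp`.
#'
#' @param icc_exp expected-scale ICC (or R-squared) in `[0, 1]`.
#' @inheritParams decompose_variance
#' @return attenuated value on the observed scale. Vectorised.
#' @examples
#' attenuate_icc(0.5, c(20, 10, 5), 0.3)  # 0.32, 0.24, 0.16
#' @export
attenuate_icc <- function(icc_exp, mean_count, cv_exp, shape = 1) {
  stopifnot(all(icc_exp >= 0), all(icc_exp <= 1))
  icc_exp * biological_proportion(mean_count, cv_exp, shape)
}

#' Observed CV of counts
#'
#' `sqrt(m/alpha + (m cv)^2) / m`: strictly decreasing in the mean count at
#' fixed expected CV, with limit `cv_exp` as the mean grows — observing more
#' events per window leaves only the biological variability.
#'
#' @inheritParams decompose_variance
#' @return dimensionless CV. Vectorised.
#' @export
observed_cv <- function(mean_count, cv_exp, shape = 1) {
  stopifnot(all(mean_count > 0), all(cv_exp >= 0), all(shape >= 1))
  sqrt(mean_count / shape + (mean_count * cv_exp)^2) / mean_count
}

#' Mean events per observation needed for a target biological proportion
#'
#' Inverts [biological_proportion()]: the mean number of observed events `m`
#' such that a fraction `target_proportion` of observed count variance is
#' biological, `m = p / (shape * cv^2 * (1 - p))`. Sampling effort should be
#' planned on the mean number of observed events, not the observation period
#' per se: the period then follows as `m / rate`.
#'
#' @param cv_exp expected CV (> 0; with no biological variation no mean
#'   count achieves a positive proportion).
#' @param target_proportion desired biological proportion, in `(0, 1)`.
#' @param shape gamma renewal shape (>= 1).
#' @return required mean events per observation. Vectorised.
#' @examples
#' plan_sampling(0.3, 0.9)  # 100 events per observation
#' @export
plan_sampling <- function(cv_exp, target_proportion, shape = 1) {
  stopifnot(all(target_proportion > 0), all(target_proportion < 1),
            all(shape >= 1))
  if (any(cv_exp <= 0)) {
    stop(paste("`cv_exp` must be > 0: with no expected-rate variation no",
               "sampling effort attains a positive biological proportion"),
         call. = FALSE)
  }
  target_proportion / (shape * cv_exp^2 * (1 - target_proportion))
}
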