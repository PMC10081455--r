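#' Construct an event series
#'
#' An event series holds the timestamps of a behaviour within one observation
#' window. Times live in the half-open window `[0, duration)`: an event
#' falling exactly at `duration` belongs to the next (unobserved) window.
#'
#' @param unit_id,obs_id identifiers for the observed unit (individual, nest)
#'   and the observation.
#' @param duration observation period in hours (> 0).
#' @param times numeric vector of event times, strictly increasing, all in
#'   `[0, duration)`. May be empty.
#' @return An object of class `event_series`: a list with fields `unit_id`,
#'   `obs_id`, `duration`, `times`. Its count is `length(times)`.
#' @export
event_series <- function(unit_id, obs_id, duration, times = numeric()) {
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop("`duration` must be a single positive number (hours)", call. = FALSE)
  }
  times <- as.numeric(times)
  if (length(times)) {
    if (any(!is.finite(times)) || any(times < 0) || any(times >= duration)) {
      stop("event times must lie in [0, duration)", call. = FALSE)
    }
    if (any(diff(times) <= 0)) {
      stop("event times must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(unit_id = as.character(unit_id), obs_id = as.character(obs_id),
         duration = duration, times = times),
    class = "event_series"
  )
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> unit %s, obs %s: %d events in %.3g h\n",
              x$unit_id, x$obs_id, length(x$times), x$duration))
  invisible(x)
}

#' @export
length.event_series <- function(x) length(x$times)

check_rate_duration <- function(rate, duration) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number (events/hour)", call. = FALSE)
  }
  if (!is.numeric(duration) || length(duration) != 1L || !is.finite(duration) ||
      duration <= 0) {
    stop("`duration` must be a single positive number (hours)", call. = FALSE)
  }
}

## Draw renewal event times on [0, duration) with gamma intervals of mean
## 1/rate and shape `shape` (ordinary renewal: the first interval has the
## same law). Intervals are drawn in chunks sized from the expected count.
renewal_times <- function(rate, shape, duration) {
  chunk <- max(16L, ceiling(rate * duration + 4 * sqrt(rate * duration / shape)))
  times <- numeric(0)
  last <- 0
  repeat {
    gaps <- rgamma(chunk, shape = shape, rate = shape * rate)
    tt <- last + cumsum(gaps)
    times <- c(times, tt)
    last <- times[length(times)]
    if (last >= duration) break
  }
  times[times < duration]
}

#' Simulate a homogeneous Poisson event series
#'
#' Events with i.i.d. exponential inter-event intervals of mean `1/rate`;
#' the count over the window is Poisson(`rate * duration`) in distribution.
#'
#' @param rate event rate in events/hour (> 0).
#' @param duration observation period in hours (> 0).
#' @param seed optional integer seed; if supplied the RNG is seeded so
#'   repeated calls are identical.
#' @param unit_id,obs_id identifiers stored on the result.
#' @return An [event_series()].
#' @examples
#' s <- simulate_poisson_events(10, 2, seed = 1)
#' length(s)
#' @export
simulate_poisson_events <- function(rate, duration, seed = NULL,
                                    unit_id = "u1", obs_id = "o1") {
  simulate_gamma_renewal(rate, shape = 1, duration = duration, seed = seed,
                         unit_id = unit_id, obs_id = obs_id)
}

#' Simulate a gamma-renewal event series with a refractory period
#'
#' Inter-event intervals are i.i.d. Gamma(shape = `shape`, mean = `1/rate`).
#' `shape = 1` is the homogeneous Poisson process; `shape > 1` gives a
#' refractory period (the interval density has mode
#' `(shape - 1) / (shape * rate)` > 0) and underdisperses counts: the
#' long-run variance/mean ratio of counts tends to `1/shape`. Clustered
#' processes (`shape < 1`) are rejected.
#'
#' @inheritParams simulate_poisson_events
#' @param shape gamma shape `alpha` >= 1 (dimensionless).
#' @return An [event_series()].
#' @export
simulate_gamma_renewal <- function(rate, shape = 1, duration, seed = NULL,
                                   unit_id = "u1", obs_id = "o1") {
  check_rate_duration(rate, duration)
  if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) ||
      shape < 1) {
    stop("`shape` must be >= 1 (clustered processes are out of scope)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  event_series(unit_id, obs_id, duration, renewal_times(rate, shape, duration))
}

#' Simulate a multi-unit observation study
#'
#' Generates an observation table under the generative model used throughout
#' the package: each observation `j` of unit `i` has a latent expected rate
#' \deqn{\lambda_{ij} = \bar\lambda \exp(b_i + e_{ij} - (\sigma^2_B +
#'   \sigma^2_E)/2)}
#' with `b_i ~ N(0, sigma2_B)` (consistent unit differences) and
#' `e_ij ~ N(0, sigma2_E)` (observation-to-observation variation). The latent
#' variances are solved so that on the arithmetic scale the coefficient of
#' variation of `lambda` equals `cv_exp` and the proportion of expected-rate
#' variance due to unit identity equals `icc_exp`:
#' `sigma2_B + sigma2_E = log(1 + cv_exp^2)` and
#' `sigma2_B = log(1 + icc_exp * cv_exp^2)`. Counts are then generated by the
#' requested renewal process at rate `lambda_ij` over `duration`.
#'
#' @param mean_rate mean event rate `lambda-bar` in events/hour (> 0).
#' @param cv_exp arithmetic-scale coefficient of variation of expected rates
#'   across observations (>= 0; 0 forces all rates equal).
#' @param icc_exp proportion of expected-rate variance due to unit identity,
#'   arithmetic scale, in `[0, 1]`.
#' @param shape gamma renewal shape (>= 1; 1 = Poisson).
#' @param n_units,obs_per_unit study dimensions (positive integers).
#' @param duration observation period in hours (> 0, recycled to all
#'   observations).
#' @param seed optional integer seed.
#' @param keep_times if `TRUE`, also return the simulated event series.
#' @return A `data.frame` (the observation table) with columns `unit_id`,
#'   `obs_id`, `duration`, `count`, carrying attributes `truth` (a data.frame
#'   of the hidden per-observation expected rates `lambda` and latent effects)
#'   and, when `keep_times = TRUE`, `series` (list of [event_series()]).
#' @examples
#' tab <- simulate_study(10, cv_exp = 0.3, icc_exp = 0.5, n_units = 20,
#'                       obs_per_unit = 5, duration = 2, seed = 1)
#' head(tab)
#' @export
simulate_study <- function(mean_rate, cv_exp, icc_exp, shape = 1,
                           n_units, obs_per_unit, duration, seed = NULL,
                           keep_times = FALSE) {
  check_rate_duration(mean_rate, duration)
  if (!is.numeric(cv_exp) || length(cv_exp) != 1L || cv_exp < 0) {
    stop("`cv_exp` must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(icc_exp) || length(icc_exp) != 1L ||
      icc_exp < 0 || icc_exp > 1) {
    stop("`icc_exp` must lie in [0, 1]", call. = FALSE)
  }
  if (shape < 1) stop("`shape` must be >= 1", call. = FALSE)
  n_units <- as.integer(n_units); obs_per_unit <- as.integer(obs_per_unit)
  if (n_units < 1L || obs_per_unit < 1L) {
    stop("`n_units` and `obs_per_unit` must be positive integers",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))

  lat <- latent_variances(cv_exp, icc_exp)
  n_obs <- n_units * obs_per_unit
  b <- rnorm(n_units, 0, sqrt(lat$sigma2_b))
  e <- rnorm(n_obs, 0, sqrt(lat$sigma2_e))
  unit_idx <- rep(seq_len(n_units), each = obs_per_unit)
  lambda <- mean_rate * exp(b[unit_idx] + e - lat$sigma2_total / 2)

  unit_id <- sprintf("u%03d", unit_idx)
  obs_id <- sprintf("u%03d_o%02d", unit_idx,
                    rep(seq_len(obs_per_unit), times = n_units))

  series <- NULL
  if (shape == 1 && !keep_times) {
    count <- rpois(n_obs, lambda * duration)
  } else {
    series <- vector("list", n_obs)
    count <- integer(n_obs)
    for (k in seq_len(n_obs)) {
      tt <- renewal_times(lambda[k], shape, duration)
      series[[k]] <- event_series(unit_id[k], obs_id[k], duration, tt)
      count[k] <- length(tt)
    }
  }

  tab <- data.frame(unit_id = unit_id, obs_id = obs_id,
                    duration = duration, count = count,
                    stringsAsFactors = FALSE)
  attr(tab, "truth") <- data.frame(
    unit_id = unit_id, obs_id = obs_id, lambda = lambda,
    b = b[unit_idx], e = e, stringsAsFactors = FALSE)
  attr(tab, "params") <- list(mean_rate = mean_rate, cv_exp = cv_exp,
                              icc_exp = icc_exp, shape = shape,
                              n_units = n_units, obs_per_unit = obs_per_unit,
                              duration = duration)
  if (keep_times) attr(tab, "series") <- series
  tab
}

## Solve the latent (log-scale) variances from arithmetic-scale targets.
latent_variances <- function(cv_exp, icc_exp) {
  sigma2_total <- log1p(cv_exp^2)
  sigma2_b <- log1p(icc_exp * cv_exp^2)
  list(sigma2_total = sigma2_total, sigma2_b = sigma2_b,
       sigma2_e = sigma2_total - sigma2_b)
}

#' Fit a gamma distribution to within-observation interval lengths
#'
#' Pools the inter-event intervals of a collection of event series and fits
#' a gamma distribution by maximum likelihood (Newton iteration on the shape
#' using the digamma score, method-of-moments start, tolerance 1e-8). The
#' fitted shape `alpha` measures the refractory period relative to the mean
#' interval: `alpha` near 1 means exponential intervals (no refractory
#' period); the refractory period itself is most intuitively the mode of the
#' fitted gamma, `(alpha - 1) * scale` when `alpha > 1`, else 0.
#'
#' @param series one [event_series()] or a list of them.
#' @param min_intervals fits with fewer pooled intervals are flagged
#'   (`low_n = TRUE`) with a warning.
#' @return An object of class `gamma_interval_fit`: list with `shape`,
#'   `mean_interval`, `scale`, `refractory_mode`, `loglik`, `n_intervals`,
#'   `low_n`.
#' @export
fit_interval_gamma <- function(series, min_intervals = 30L) {
  if (inherits(series, "event_series")) series <- list(series)
  if (!length(series) || !all(vapply(series, inherits, TRUE, "event_series"))) {
    stop("`series` must be an event_series or a list of them", call. = FALSE)
  }
  gaps <- unlist(lapply(series, function(s) diff(s$times)), use.names = FALSE)
  if (!length(gaps)) {
    stop(paste("no intervals: every series has fewer than two events;",
               "interval fitting needs at least one within-observation gap"),
         call. = FALSE)
  }
  low_n <- length(gaps) < min_intervals
  if (low_n) {
    warning(sprintf("only %d intervals pooled (< %d); fit will be imprecise",
                    length(gaps), min_intervals), call. = FALSE)
  }
  xbar <- mean(gaps)
  s <- log(xbar) - mean(log(gaps))  # always >= 0 (Jensen); 0 iff constant
  if (s < 1e-12) {
    warning("intervals are (near-)constant; shape estimate is unbounded",
            call. = FALSE)
    a <- 1e8
  } else {
    a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # moment-style start
    for (it in 1:100) {
      f <- log(a) - digamma(a) - s
      step <- f / (1 / a - trigamma(a))
      a_new <- a - step
      if (a_new <= 0) a_new <- a / 2
      if (abs(a_new - a) < 1e-8 * max(1, a)) { a <- a_new; break }
      a <- a_new
    }
  }
  scale <- xbar / a
  structure(
    list(shape = a, mean_interval = xbar, scale = scale,
         refractory_mode = if (a > 1) (a - 1) * scale else 0,
         loglik = sum(dgamma(gaps, shape = a, scale = scale, log = TRUE)),
         n_intervals = length(gaps), low_n = low_n),
    class = "gamma_interval_fit"
  )
}

#' @export
print.gamma_interval_fit <- function(x, ...) {
  cat("Gamma interval fit\n")
  cat(sprintf("  intervals: %d%s\n", x$n_intervals,
              if (x$low_n) " (low-n warning)" else ""))
  cat(sprintf("  shape (alpha): %.4g   mean interval: %.4g h\n",
              x$shape, x$mean_interval))
  cat(sprintf("  refractory period (gamma mode): %.4g h\n", x$refractory_mode))
  cat(sprintf("  log-likelihood: %.4g\n", x$loglik))
  invisible(x)
}
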