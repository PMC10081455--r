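#' SD from a standard error and sample size
#'
#' @param se standard error (>= 0).
#' @param n sample size (>= 1).
#' @return `se * sqrt(n)`. Vectorised.
#' @export
sd_from_se <- function(se, n) {
  stopifnot(all(se >= 0), all(n >= 1))
  se * sqrt(n)
}

#' SD estimated from a range and/or interquartile range
#'
#' Normal-theory estimators (Wan et al. family) for recovering a standard
#' deviation from published order statistics. The variant is selected from
#' what is available: range only, IQR only, or both (averaging the two
#' half-width estimators); the choice is recorded in the `method` attribute.
#'
#' @param n sample size (>= 2).
#' @param range_low,range_high sample minimum and maximum (optional).
#' @param iqr_low,iqr_high first and third quartiles (optional).
#' @return estimated SD with attribute `method` in
#'   `c("range", "iqr", "range+iqr")`.
#' @export
sd_from_range <- function(n, range_low = NULL, range_high = NULL,
                          iqr_low = NULL, iqr_high = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 2)
  have_range <- !is.null(range_low) && !is.null(range_high) &&
    is.finite(range_low) && is.finite(range_high)
  have_iqr <- !is.null(iqr_low) && !is.null(iqr_high) &&
    is.finite(iqr_low) && is.finite(iqr_high)
  if (!have_range && !have_iqr) {
    stop("need a range and/or an interquartile range", call. = FALSE)
  }
  if (have_range && range_high < range_low) {
    stop("range_high < range_low", call. = FALSE)
  }
  if (have_iqr && iqr_high < iqr_low) stop("iqr_high < iqr_low", call. = FALSE)
  xi_range <- 2 * qnorm((n - 0.375) / (n + 0.25))
  xi_iqr <- 2 * qnorm((0.75 * n - 0.125) / (n + 0.25))
  if (have_range && have_iqr) {
    est <- (range_high - range_low) / (2 * xi_range) +
      (iqr_high - iqr_low) / (2 * xi_iqr)
    method <- "range+iqr"
  } else if (have_range) {
    est <- (range_high - range_low) / xi_range
    method <- "range"
  } else {
    est <- (iqr_high - iqr_low) / xi_iqr
    method <- "iqr"
  }
  structure(est, method = method)
}

#' Pool subgroup means and SDs into one sample summary
#'
#' When a publication reports summaries per subgroup (e.g. per sex) but the
#' analysis used all data, the `M` subgroup estimates are pooled with the
#' sample-size-weighted mean and the exact pooled SD, which includes the
#' spread of the subgroup means around the pooled mean:
#' \deqn{\sigma_x = \sqrt{\frac{1}{\sum N_i - 1}\left(\sum\left[(N_i - 1)
#'   \sigma_i^2 + N_i \bar x_i^2\right] - (\sum N_i)\,\bar x^2\right)}}
#'
#' @param mean,sd,n equal-length vectors of subgroup means, SDs and sizes.
#'   Alternatively `mean` may be a data.frame with columns `mean`, `sd`, `n`.
#' @return list with `mean`, `sd`, `n` (totals for the pooled sample).
#' @examples
#' pool_groups(c(8, 12), c(2, 2), c(10, 10))
#' @export
pool_groups <- function(mean, sd = NULL, n = NULL) {
  if (is.data.frame(mean)) {
    df <- mean; mean <- df$mean; sd <- df$sd; n <- df$n
  }
  if (is.null(sd) || is.null(n) || length(mean) != length(sd) ||
      length(mean) != length(n)) {
    stop("`mean`, `sd`, `n` must be equal-length vectors", call. = FALSE)
  }
  if (anyNA(mean) || anyNA(sd) || anyNA(n)) {
    stop("incomplete input: every group needs mean, sd and n", call. = FALSE)
  }
  stopifnot(all(n >= 1), all(sd >= 0))
  N <- sum(n)
  if (N < 2) stop("total n must be at least 2", call. = FALSE)
  xbar <- sum(n * mean) / N
  ss <- sum((n - 1) * sd^2 + n * mean^2) - N * xbar^2
  list(mean = xbar, sd = sqrt(ss / (N - 1)), n = N)
}

#' Rescale a published mean and SD between rate and count scales
#'
#' Published summaries presented as rates (e.g. visits/hour) are returned to
#' the scale on which they were collected by multiplying both mean and SD by
#' `observation_period / presented_per`. The same function demonstrates the
#' transformation artefact in the other direction: shrinking the mean (count
#' to per-hour with period > 1 h) deflates the recoverable expected CV,
#' enlarging it inflates it, because the stochastic variance equals the mean
#' only on the count scale.
#'
#' @param mean,sd summary on the presented scale.
#' @param observation_period length of the actual observation window (hours).
#' @param presented_per time base of the presented rate (hours; 1 for
#'   per-hour rates, equal to `observation_period` for raw counts).
#' @return list with `mean`, `sd` on the count scale and the `factor`
#'   applied.
#' @examples
#' rescale_to_count(2.5, 1.0, observation_period = 4)  # mean 10, sd 4
#' @export
rescale_to_count <- function(mean, sd, observation_period, presented_per = 1) {
  stopifnot(observation_period > 0, presented_per > 0)
  f <- observation_period / presented_per
  list(mean = mean * f, sd = if (is.null(sd)) NULL else sd * f, factor = f)
}

#' Back-calculate a per-chick rate to a whole-brood mean
#'
#' Multiplies a per-chick mean by the (mean) brood size. The SD cannot be
#' recovered this way (the per-chick transformation does not commute with the
#' dispersion summaries typically reported), so it is deliberately left
#' unset and flagged; such estimates are excluded from expected-CV summaries
#' downstream.
#'
#' @param mean_per_chick published per-chick mean.
#' @param brood_size mean brood size (> 0).
#' @return list with `mean`, `sd = NA`, and flag
#'   `per_chick_sd_unavailable = TRUE`.
#' @export
unscale_per_chick <- function(mean_per_chick, brood_size) {
  stopifnot(brood_size > 0)
  list(mean = mean_per_chick * brood_size, sd = NA_real_,
       per_chick_sd_unavailable = TRUE)
}

#' Read a literature-survey table
#'
#' Expects a comma-separated file with header columns `study_id, species,
#' mean, sd, se, n, range_low, range_high, iqr_low, iqr_high, period_h,
#' rate_basis, brood_size, uses`; empty cells are missing values.
#' `rate_basis` is one of `count`, `per-hour`, `per-hour-per-chick`.
#'
#' @param path file path.
#' @return data.frame ready for [summarise_survey()].
#' @export
read_survey_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  needed <- c("study_id", "mean", "n", "period_h", "rate_basis")
  miss <- setdiff(needed, names(df))
  if (length(miss)) {
    stop("survey table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("species", "sd", "se", "range_low", "range_high",
                "iqr_low", "iqr_high", "brood_size", "uses")) {
    if (!col %in% names(df)) df[[col]] <- NA
  }
  df
}

weighted_median <- function(x, w) {
  keep <- is.finite(x) & is.finite(w) & w > 0
  median(rep(x[keep], times = round(w[keep])))
}

#' Standardise and summarise a table of published count summaries
#'
#' For each estimate: derive an SD from SE or range/IQR when no SD is given;
#' rescale rate-presented summaries back to the count scale using the
#' observation period; back-calculate per-chick means (dropping the SD, with
#' a flag); compute the expected CV (0 with an `underdispersed` flag when the
#' variance does not exceed the mean) and the biological proportion of
#' observed variance. Medians over estimates include the zero-assigned
#' underdispersed values; estimates with no recoverable SD contribute to the
#' mean-count summary only. Both unweighted medians (one row, one vote) and
#' medians weighted by the `uses` column (how many analyses reused the
#' dataset) are reported.
#'
#' @param estimates data.frame as returned by [read_survey_table()], or any
#'   data.frame with those columns.
#' @return An object of class `survey_summary`: list with the per-estimate
#'   `table` (count-scale mean/sd, cv_exp, proportion_biological, flags) and
#'   `summary` (n_estimates, n_with_sd, n_underdispersed, medians and ranges,
#'   weighted medians).
#' @export
summarise_survey <- function(estimates) {
  if (!is.data.frame(estimates) || !nrow(estimates)) {
    stop("`estimates` must be a non-empty data.frame", call. = FALSE)
  }
  est <- estimates
  if (is.null(est$uses)) est$uses <- 1
  est$uses[is.na(est$uses)] <- 1
  out <- data.frame(study_id = est$study_id, stringsAsFactors = FALSE)
  n_rows <- nrow(est)
  out$mean_count <- out$sd_count <- rep(NA_real_, n_rows)
  out$cv_exp <- out$proportion_biological <- rep(NA_real_, n_rows)
  out$underdispersed <- out$per_chick_sd_unavailable <- rep(FALSE, n_rows)
  out$uses <- est$uses

  for (i in seq_len(n_rows)) {
    m <- est$mean[i]; s <- est$sd[i]
    if (is.na(m)) next
    if (is.na(s) && !is.na(est$se[i]) && !is.na(est$n[i])) {
      s <- sd_from_se(est$se[i], est$n[i])
    }
    if (is.na(s) && !is.na(est$n[i])) {
      rl <- est$range_low[i]; rh <- est$range_high[i]
      il <- est$iqr_low[i]; ih <- est$iqr_high[i]
      if ((!is.na(rl) && !is.na(rh)) || (!is.na(il) && !is.na(ih))) {
        s <- as.numeric(sd_from_range(
          est$n[i],
          range_low = if (is.na(rl)) NULL else rl,
          range_high = if (is.na(rh)) NULL else rh,
          iqr_low = if (is.na(il)) NULL else il,
          iqr_high = if (is.na(ih)) NULL else ih))
      }
    }
    basis <- est$rate_basis[i]
    if (identical(basis, "per-hour-per-chick")) {
      if (is.na(est$brood_size[i])) next
      m <- unscale_per_chick(m, est$brood_size[i])$mean
      s <- NA_real_
      out$per_chick_sd_unavailable[i] <- TRUE
      basis <- "per-hour"
    }
    if (identical(basis, "per-hour")) {
      sc <- rescale_to_count(m, if (is.na(s)) NULL else s,
                             observation_period = est$period_h[i],
                             presented_per = 1)
      m <- sc$mean
      if (!is.null(sc$sd)) s <- sc$sd
    }
    out$mean_count[i] <- m
    out$sd_count[i] <- s
    if (!is.na(s) && m > 0) {
      cv <- expected_cv(m, s)
      out$underdispersed[i] <- is_underdispersed(cv)
      out$cv_exp[i] <- as.numeric(cv)
      out$proportion_biological[i] <- biological_proportion(m, as.numeric(cv))
    }
  }

  has_cv <- !is.na(out$cv_exp)
  summary <- list(
    n_estimates = n_rows,
    n_with_mean = sum(!is.na(out$mean_count)),
    n_with_sd = sum(!is.na(out$sd_count)),
    n_underdispersed = sum(out$underdispersed),
    n_per_chick_dropped = sum(out$per_chick_sd_unavailable),
    median_mean_count = median(out$mean_count, na.rm = TRUE),
    median_cv_exp = median(out$cv_exp[has_cv]),
    range_cv_exp = if (any(has_cv)) range(out$cv_exp[has_cv]) else c(NA, NA),
    median_proportion = median(out$proportion_biological[has_cv]),
    range_proportion = if (any(has_cv)) {
      range(out$proportion_biological[has_cv])
    } else c(NA, NA),
    weighted_median_mean_count =
      weighted_median(out$mean_count, out$uses),
    weighted_median_cv_exp = weighted_median(out$cv_exp, out$uses),
    weighted_median_proportion =
      weighted_median(out$proportion_biological, out$uses)
  )
  structure(list(table = out, summary = summary), class = "survey_summary")
}

#' @export
print.survey_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Survey of %d published estimates (%d with usable SD, %d underdispersed -> CV 0)\n",
              s$n_estimates, s$n_with_sd, s$n_underdispersed))
  cat(sprintf("  median mean count          : %.3g\n", s$median_mean_count))
  cat(sprintf("  median expected CV         : %.3g (range %.3g-%.3g)\n",
              s$median_cv_exp, s$range_cv_exp[1], s$range_cv_exp[2]))
  cat(sprintf("  median biological proportion: %.3g\n", s$median_proportion))
  invisible(x)
}
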