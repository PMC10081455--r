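# Shared simulated studies (moderate size keeps the suite quick; MC bands
# below are sized for these dimensions).
study_a_tab <- simulate_study(10, 0.3, 0.5, n_units = 200, obs_per_unit = 5,
                              duration = 2, seed = 31)
study_c_tab <- simulate_study(10, 0.3, 0.5, n_units = 200, obs_per_unit = 5,
                              duration = 0.5, seed = 32)

test_that("rates and malformed tables are rejected with the raw-count rule", {
  bad <- study_a_tab
  bad$count <- bad$count / bad$duration + 0.5
  expect_error(fit_count_glmm(bad), "raw number")
  expect_error(fit_count_glmm(study_a_tab[, c("unit_id", "count")]),
               "missing columns")
  few <- simulate_study(10, 0.3, 0.5, n_units = 5, obs_per_unit = 2,
                        duration = 1, seed = 1)
  expect_warning(fit_count_glmm(few), "units")
})

test_that("Poisson-lognormal GLMM recovers the expected-scale ICC", {
  fit <- fit_count_glmm(study_a_tab)
  expect_true(fit$converged)
  expect_true(fit$offset_used)
  rep <- icc_report(fit, reference_duration = 2)
  expect_lt(abs(rep$icc_expected - 0.5), 0.1)
  # latent total variance should match the lognormal construction
  expect_lt(abs(fit$var_between + fit$var_olre - log1p(0.09)), 0.03)
  # between-unit latent SD is CV_B
  expect_equal(rep$cv_b, sqrt(fit$var_between))
})

test_that("null between-unit variance is recovered as (near) zero", {
  est <- vapply(1:10, function(i) {
    tab <- simulate_study(10, 0.3, icc_exp = 0, n_units = 60,
                          obs_per_unit = 4, duration = 2, seed = 100 + i)
    suppressWarnings(fit_count_glmm(tab))$var_between
  }, numeric(1))
  expect_lt(mean(est), 0.01)
})

test_that("changing time units only shifts the latent intercept by log(60)", {
  minutes <- study_a_tab
  minutes$duration <- minutes$duration * 60
  f_h <- fit_count_glmm(study_a_tab)
  f_m <- fit_count_glmm(minutes)
  expect_equal(f_m$intercept_latent, f_h$intercept_latent - log(60),
               tolerance = 1e-4)
  expect_equal(f_m$var_between, f_h$var_between, tolerance = 1e-4)
  expect_equal(f_m$var_olre, f_h$var_olre, tolerance = 1e-4)
})

test_that("ICC report scales behave: bounds, degeneracy, duration growth", {
  fit <- fit_count_glmm(study_a_tab)
  rep <- icc_report(fit, reference_duration = 2)
  expect_lte(rep$icc_observed, rep$icc_expected)
  # observed-scale ICC rises toward the latent ratio as the window grows
  grid <- vapply(c(0.25, 0.5, 1, 2, 4, 100),
                 function(h) icc_report(fit, h)$icc_observed, numeric(1))
  expect_true(all(diff(grid) > 0))
  expect_lt(abs(grid[6] - rep$icc_latent), 0.01)
  # degenerate: no observation-level variance means ICC 1 on both scales
  fake <- fit
  fake$var_olre <- 0
  expect_equal(icc_report(fake, 1)$icc_latent, 1)
  expect_equal(icc_report(fake, 1)$icc_expected, 1)
  nc <- fit
  nc$converged <- FALSE
  expect_error(icc_report(nc, 1), "converge")
})

test_that("two routes to the observed-scale ICC concur (report vs calculus)", {
  fit <- fit_count_glmm(study_a_tab)
  rep <- icc_report(fit, reference_duration = 2)
  analytic <- attenuate_icc(0.5, 20, 0.3)
  expect_lt(abs(rep$icc_observed - analytic), 0.06)
  naive <- fit_naive_lmm(study_a_tab, "count")
  expect_lt(abs(naive$icc_observed - analytic), 0.06)
})

test_that("naive Gaussian analyses show the predicted attenuation", {
  naive_a <- fit_naive_lmm(study_a_tab, "count")
  expect_true(naive_a$biased_comparator)
  expect_lt(abs(naive_a$icc_observed - 0.32), 0.06)
  naive_c <- fit_naive_lmm(study_c_tab, "count")
  expect_lt(abs(naive_c$icc_observed - 0.16), 0.06)
  # with equal durations, dividing by t rescales both variance components
  # identically, so the rate analysis hides (not fixes) the problem
  naive_rate <- fit_naive_lmm(study_c_tab, "rate")
  expect_equal(naive_rate$icc_observed, naive_c$icc_observed,
               tolerance = 1e-6)
})

test_that("errors-in-variables regression undoes predictor attenuation", {
  b_true <- 0.5
  tab <- simulate_study(10, 0.3, 0.5, n_units = 100, obs_per_unit = 5,
                        duration = 1, seed = 41)
  set.seed(42)
  lam <- attr(tab, "truth")$lambda
  tab$outcome <- 1 + b_true * lam + rnorm(nrow(tab), 0, 1)
  eiv <- fit_error_in_variable(tab)
  expect_true(eiv$converged)
  expect_lt(abs(eiv$slope - b_true) / b_true, 0.15)
  expect_gt(eiv$ci["slope", "upper"], eiv$slope)  # interval contains point
  expect_lt(eiv$ci["slope", "lower"], eiv$slope)
  # the naive slope is attenuated by about the biological proportion
  naive <- stats::coef(stats::lm(outcome ~ I(count / duration), data = tab))
  shrink <- unname(naive[2]) / b_true
  expect_lt(abs(shrink - biological_proportion(10, 0.3)), 0.12)
  # latent rate distribution recovered
  expect_lt(abs(eiv$latent_rate_mean - 10) / 10, 0.1)
})

test_that("EIV interval covers a null slope and error converges away", {
  covered <- vapply(1:10, function(i) {
    tab <- simulate_study(10, 0.3, 0.5, n_units = 40, obs_per_unit = 3,
                          duration = 1, seed = 200 + i)
    tab$outcome <- rnorm(nrow(tab), 5, 1)
    f <- suppressWarnings(fit_error_in_variable(tab))
    f$ci["slope", "lower"] <= 0 && f$ci["slope", "upper"] >= 0
  }, logical(1))
  expect_gte(sum(covered), 8)
  # at a large mean count the naive and EIV slopes converge
  gap <- vapply(c(10, 100), function(m) {
    tab <- simulate_study(m, 0.3, 0.5, n_units = 100, obs_per_unit = 5,
                          duration = 1, seed = 300 + m)
    set.seed(301 + m)
    tab$outcome <- 0.5 * attr(tab, "truth")$lambda + rnorm(nrow(tab), 0, 1)
    naive <- stats::coef(stats::lm(outcome ~ I(count / duration),
                                   data = tab))[2]
    abs(unname(naive) - fit_error_in_variable(tab)$slope)
  }, numeric(1))
  expect_lt(gap[2], gap[1])
})

test_that("EIV rejects degenerate outcomes and missing columns", {
  tab <- study_a_tab
  expect_error(fit_error_in_variable(tab), "outcome")
  tab$outcome <- 3
  expect_error(fit_error_in_variable(tab), "constant")
})

test_that("negative-binomial backend fits and returns unit variance", {
  skip_if_not_installed("glmmTMB")
  fit <- fit_count_glmm(study_a_tab, family = "nbinom")
  expect_true(fit$converged)
  expect_gt(fit$var_between, 0)
  expect_true(is.na(fit$var_olre))
  expect_error(icc_report(fit, 1), "Poisson")
})
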