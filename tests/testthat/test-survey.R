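test_that("SE-to-SD conversion and its roundtrip hold", {
  expect_equal(sd_from_se(2, 25), 10)
  expect_equal(sd_from_se(0, 7), 0)
  set.seed(4)
  for (i in 1:10) {
    s <- runif(1, 0.1, 5); n <- sample(2:200, 1)
    expect_equal(sd_from_se(s / sqrt(n), n), s)
  }
})

test_that("pooled moments equal sample moments of concatenated data", {
  # single group is the identity
  one <- pool_groups(7.3, 2.1, 12)
  expect_equal(one$mean, 7.3)
  expect_equal(one$sd, 2.1)
  # equal-mean groups: pooling only reweights the SDs
  two <- pool_groups(c(10, 10), c(2, 2), c(10, 10))
  expect_equal(two$mean, 10)
  expect_equal(round(two$sd, 3), 1.947)
  # mean spread inflates the pooled SD beyond the within-group SDs
  spread <- pool_groups(c(8, 12), c(2, 2), c(10, 10))
  expect_gt(spread$sd, 2)
  # concatenation oracle over random configurations
  set.seed(5)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    means <- runif(k, 2, 30); sds <- runif(k, 0.5, 6)
    ns <- sample(5:40, k, replace = TRUE)
    oracle <- pool_by_concatenation(means, sds, ns)
    got <- pool_groups(means, sds, ns)
    expect_equal(got$mean, oracle$mean, tolerance = 1e-8)
    expect_equal(got$sd, oracle$sd, tolerance = 1e-8)
    expect_equal(got$n, oracle$n)
  }
  expect_error(pool_groups(c(1, 2), c(1, NA), c(5, 5)), "incomplete")
})

test_that("rate/count rescaling works, inverts, and shows the artefact", {
  r <- rescale_to_count(2.5, 1.0, observation_period = 4)
  expect_equal(r$mean, 10)
  expect_equal(r$sd, 4)
  ident <- rescale_to_count(3, 1, observation_period = 2, presented_per = 2)
  expect_equal(ident$mean, 3)
  # inverse roundtrip to machine precision
  fwd <- rescale_to_count(20, 7.5, observation_period = 1, presented_per = 2)
  back <- rescale_to_count(fwd$mean, fwd$sd, observation_period = 2,
                           presented_per = 1)
  expect_equal(back$mean, 20)
  expect_equal(back$sd, 7.5)
  # shrinking the mean deflates the recoverable expected CV (and vice versa)
  study_a <- rescale_to_count(20, 7.5, observation_period = 1,
                              presented_per = 2)
  expect_equal(round(as.numeric(expected_cv(study_a$mean, study_a$sd)), 1),
               0.2)
  study_c <- rescale_to_count(5, 2.7, observation_period = 1,
                              presented_per = 0.5)
  expect_equal(round(as.numeric(expected_cv(study_c$mean, study_c$sd)), 3),
               0.438)
  set.seed(6)
  for (i in 1:20) {
    m <- runif(1, 8, 40); cv <- runif(1, 0.2, 0.8)
    s <- decompose_variance(m, cv)$sd_observed
    true_cv <- as.numeric(expected_cv(m, s))
    down <- rescale_to_count(m, s, 1, presented_per = 2)     # halve the mean
    up <- rescale_to_count(m, s, 2, presented_per = 1)       # double it
    expect_lt(as.numeric(expected_cv(down$mean, down$sd)), true_cv)
    expect_gt(as.numeric(expected_cv(up$mean, up$sd)), true_cv)
  }
})

test_that("per-chick back-calculation keeps the mean and drops the SD", {
  u <- unscale_per_chick(3, 4)
  expect_equal(u$mean, 12)
  expect_true(is.na(u$sd))
  expect_true(u$per_chick_sd_unavailable)
  expect_equal(unscale_per_chick(5, 1)$mean, 5)
})

test_that("range/IQR SD estimators recover a normal SD (simulation oracle)", {
  set.seed(7)
  n <- 25
  ests <- t(replicate(400, {
    x <- rnorm(n, 10, 2)
    q <- quantile(x, c(0.25, 0.75))
    c(range = as.numeric(sd_from_range(n, range_low = min(x),
                                       range_high = max(x))),
      iqr = as.numeric(sd_from_range(n, iqr_low = q[1], iqr_high = q[2])),
      both = as.numeric(sd_from_range(n, min(x), max(x), q[1], q[2])))
  }))
  expect_lt(abs(mean(ests[, "range"]) - 2), 0.15)
  expect_lt(abs(mean(ests[, "iqr"]) - 2), 0.15)
  expect_lt(abs(mean(ests[, "both"]) - 2), 0.15)
  expect_equal(attr(sd_from_range(10, 0, 4), "method"), "range")
  expect_equal(attr(sd_from_range(10, iqr_low = 1, iqr_high = 3), "method"),
               "iqr")
  expect_error(sd_from_range(10), "range")
})

make_survey_fixture <- function() {
  data.frame(
    study_id = c("s1", "s2", "s3", "s4", "s5"),
    species = "sp",
    # s1: count scale with sd; s2: per-hour over 2 h; s3: underdispersed;
    # s4: per-chick (no sd downstream); s5: se only
    mean = c(20, 10, 6, 2.5, 15),
    sd = c(7.5, NA, 2, NA, NA),
    se = c(NA, NA, NA, NA, 1.2),
    n = c(30, 25, 40, 20, 36),
    range_low = NA, range_high = NA, iqr_low = NA, iqr_high = NA,
    period_h = c(2, 2, 1, 1, 1),
    rate_basis = c("count", "per-hour", "count", "per-hour-per-chick",
                   "count"),
    brood_size = c(NA, NA, NA, 4, NA),
    uses = c(1, 1, 2, 1, 1),
    stringsAsFactors = FALSE
  )
}

test_that("survey summaries standardise, flag, and take medians correctly", {
  fx <- make_survey_fixture()
  fx$sd[2] <- NA; fx$se[2] <- 0.9  # per-hour with SE
  s <- summarise_survey(fx)
  tab <- s$table
  # s2 rescaled to the 2-h count scale: mean 20, sd = 0.9*sqrt(25)*2 = 9
  expect_equal(tab$mean_count[2], 20)
  expect_equal(tab$sd_count[2], 9)
  # s3 is underdispersed (sd^2 = 4 < mean 6): cv 0, proportion 0, flagged
  expect_true(tab$underdispersed[3])
  expect_equal(tab$cv_exp[3], 0)
  expect_equal(tab$proportion_biological[3], 0)
  # s4: per-chick mean back-calculated (2.5 * 4 = 10), no sd, no cv
  expect_equal(tab$mean_count[4], 10)
  expect_true(tab$per_chick_sd_unavailable[4])
  expect_true(is.na(tab$cv_exp[4]))
  # estimates without SD are excluded from cv/proportion medians
  expect_equal(s$summary$n_with_sd, 4)
  expect_equal(s$summary$n_underdispersed, 1)
  # medians include the zero-assigned underdispersed estimate
  props <- tab$proportion_biological[!is.na(tab$proportion_biological)]
  expect_equal(s$summary$median_proportion, median(props))
  expect_true(0 %in% props)
  # weighted median repeats s3 (uses = 2)
  expect_equal(s$summary$weighted_median_proportion,
               median(rep(props, times = tab$uses[!is.na(tab$proportion_biological)])))
  expect_error(summarise_survey(data.frame()), "non-empty")
})

test_that("simple proportion medians behave as expected", {
  fx <- data.frame(study_id = c("a", "b", "c"), species = "sp",
                   mean = c(10, 10, 10),
                   sd = sqrt(10 + 100 * c(0.2, 0.5, 0.9) /
                               (1 - c(0.2, 0.5, 0.9)) / 10),
                   se = NA, n = 20, range_low = NA, range_high = NA,
                   iqr_low = NA, iqr_high = NA, period_h = 1,
                   rate_basis = "count", brood_size = NA, uses = 1,
                   stringsAsFactors = FALSE)
  s <- summarise_survey(fx)
  expect_equal(s$summary$median_proportion, 0.5, tolerance = 1e-8)
})

test_that("survey tables roundtrip through disk with schema validation", {
  fx <- make_survey_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(fx, path, row.names = FALSE)
  back <- read_survey_table(path)
  expect_equal(back$mean, fx$mean)
  expect_equal(summarise_survey(back)$summary$median_mean_count,
               summarise_survey(fx)$summary$median_mean_count)
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(fx[, setdiff(names(fx), "mean")], bad, row.names = FALSE)
  expect_error(read_survey_table(bad), "missing columns")
})
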