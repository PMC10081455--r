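# Independent oracles used across the suite.

# Anderson-Darling statistic against a fully specified continuous
# distribution, via its probability transform u = F(x). Asymptotic critical
# value at alpha = 0.01 is 3.857 (distribution-free for a fully specified F).
ad_statistic <- function(u) {
  u <- sort(u)
  n <- length(u)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}
AD_CRIT_01 <- 3.857

# Construct a sample of size n with *exactly* the given mean and sd
# (standardise a normal draw, then rescale). Used as the concatenation
# oracle for pooled-moment formulas.
sample_with_moments <- function(n, mean, sd) {
  z <- rnorm(n)
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}

# Pooled mean/sd oracle: concatenate exact-moment samples and take plain
# sample statistics.
pool_by_concatenation <- function(means, sds, ns) {
  x <- unlist(mapply(sample_with_moments, ns, means, sds, SIMPLIFY = FALSE))
  list(mean = mean(x), sd = stats::sd(x), n = length(x))
}

# Monte-Carlo oracle for the biological proportion of observed count
# variance: simulate lognormally heterogeneous Poisson counts directly.
mc_biological_proportion <- function(mean_count, cv_exp, n = 1e5) {
  s2 <- log1p(cv_exp^2)
  lam <- mean_count * exp(rnorm(n, 0, sqrt(s2)) - s2 / 2)
  y <- rpois(n, lam)
  var(lam) / var(y)
}

# Mode of a gamma density found numerically from the density itself
# (independent of the (shape-1)*scale closed form under test).
gamma_mode_numeric <- function(shape, scale) {
  stats::optimize(function(x) dgamma(x, shape = shape, scale = scale),
                  interval = c(0, shape * scale * 2), maximum = TRUE)$maximum
}
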