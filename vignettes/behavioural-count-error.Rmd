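---
title: "Stochastic error in behavioural counts: model, corrections, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic error in behavioural counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countproc)
```

## The model

A behaviour observed by counting events in a window of length $t$ hours is
described as a point process. The null model is the homogeneous Poisson
process: a single rate $\lambda$ (events/hour), exponential inter-event
intervals, and counts $y \sim \mathrm{Poisson}(\lambda t)$. The Poisson
variance $\bar{\lambda t}$ is *stochastic error*: variation between
observations that exists even when every observation has the same expected
rate. Biological variation enters as heterogeneity in the expected rates
themselves; writing its coefficient of variation as $CV_{exp}$ (which is
invariant to the window length, since mean and SD of $\lambda t$ scale
together), the observed count variance is

$$\sigma^2_y \;=\; \underbrace{\bar{\lambda t}/\alpha}_{\text{stochastic}}
\;+\; \underbrace{(\bar{\lambda t}\, CV_{exp})^2}_{\text{biological}},$$

where $\alpha \ge 1$ is the gamma-renewal shape: $\alpha = 1$ is the
Poisson process, $\alpha > 1$ a refractory period (intervals
$\sim \Gamma(\alpha, \text{mean } 1/\lambda)$, count Fano factor tending to
$1/\alpha$, refractory period interpretable as the interval-density mode
$(\alpha - 1)/(\alpha\lambda)$). Clustered processes ($\alpha < 1$) and
time-varying rates are out of scope.

Because the stochastic term grows linearly with the mean count $m =
\bar{\lambda t}$ while the biological term grows quadratically, the
proportion of observed variance that is biological,
$p = \alpha m CV^2 / (1 + \alpha m CV^2)$, rises with sampling effort.
Any ICC or $R^2$ computed from raw counts without modelling the stochastic
term is capped by $p$ and attenuated by the factor $p$; `attenuate_icc()`
and `biological_proportion()` implement exactly this algebra, and
`plan_sampling()` inverts it. Effort should be planned on the *mean number
of observed events*, not the window length per se: $m$ alone sets $p$.

## The generator and what it emulates

`simulate_study()` is the package's definition of the study conditions used
throughout the tests. Expected rates are lognormal,

$$\lambda_{ij} = \bar\lambda\,
\exp\!\big(b_i + e_{ij} - \tfrac{\sigma^2_B + \sigma^2_E}{2}\big),
\qquad b_i \sim N(0, \sigma^2_B),\; e_{ij} \sim N(0, \sigma^2_E),$$

with the latent variances solved from the *arithmetic-scale* targets the
user supplies: $\sigma^2_B + \sigma^2_E = \ln(1 + CV_{exp}^2)$ and
$\sigma^2_B = \ln(1 + \mathrm{ICC}_{exp} CV_{exp}^2)$, so that
$\mathrm{E}[\lambda] = \bar\lambda$, the arithmetic CV of $\lambda$ equals
`cv_exp`, and the unit share of arithmetic rate variance equals `icc_exp`.
The lognormal family was chosen because it makes simulation and inference a
closed loop: the fitted model (below) is exactly the Poisson-lognormal
GLMM, so parameter-recovery tests are interpretable as estimator checks,
not as family-mismatch checks. Other heterogeneity families (gamma rates,
bimodal mixtures) are equally plausible biologically and are *not*
emulated; passing recovery tests here says the estimators work under
lognormal heterogeneity, not that real data is lognormal.

Other generator choices, fixed once:

* **Ordinary renewal start.** The first interval of a refractory series is
  drawn from the same gamma as the rest rather than from the equilibrium
  (inspection-paradox) distribution. The bias this induces on counts is
  $O(1)$ in the first interval only and negligible for $\lambda t \ge 5$;
  the tolerance bands of all tests at $\lambda t \ge 20$ absorb it. A
  documented limitation for very short windows.
* **Half-open window** $[0, t)$: an event exactly at $t$ belongs to the
  next, unobserved window; counts and interval sets are therefore
  unambiguous.
* **Seeding.** One integer seed initialises R's Mersenne-Twister stream
  per call; identical parameters and seed give bit-identical tables (the
  reproducibility contract). Per-unit counter-based substreams were
  considered for parallel generation and rejected: base R has no
  counter-based generator, and the package generates nothing in parallel.
* **Default study conditions.** The worked example population — mean rate
  10 events/hour, $CV_{exp} = 0.3$, expected-scale ICC 0.5, windows of
  2 / 1 / 0.5 h — is used as the canonical fixture (`make_fixtures()`),
  giving mean counts 20, 10 and 5 and observed-scale repeatabilities 0.32,
  0.24 and 0.16.

## Estimators

**Response side.** `fit_count_glmm()` fits
`count ~ ... + (1|unit) + (1|observation)` with Poisson errors, log link,
and `log(duration)` as an offset (exposure model; slope fixed at 1), by
Laplace approximation (`lme4::glmer`). Counts are used raw — a table whose
count column is non-integral is rejected outright, because dividing by
time before fitting destroys the mean–variance identity the correction
relies on. The observation-level random effect (OLRE) carries the
overdispersion, so $\hat\sigma^2_B$ (unit) and $\hat\sigma^2_E$ (OLRE)
estimate the biological variance components free of stochastic error. A
negative-binomial (Poisson-gamma) backend is available via `glmmTMB` for
users who prefer multiplicative overdispersion; it does not feed
`icc_report()`.

`icc_report()` returns three scales:

* latent: $\sigma^2_B / (\sigma^2_B + \sigma^2_E)$;
* expected (arithmetic): $(e^{\sigma^2_B} - 1)/(e^{\sigma^2_B + \sigma^2_E} - 1)$
  — the biologically meaningful repeatability, and the scale on which the
  worked examples are stated; both are reported because the latent ratio is
  what quantitative-genetic software returns;
* observed: the latent ratio with the Poisson distribution-specific
  variance $\ln(1 + 1/\bar m')$ added to the denominator, where
  $\bar m' = \exp(\hat\beta_0 + (\sigma^2_B + \sigma^2_E)/2)\cdot t_{ref}$
  is the mean count at a user-chosen reference duration. This
  lognormal-Poisson approximation is the standard latent-scale conversion
  for Poisson GLMMs; it reproduces the analytic attenuation curve within
  Monte-Carlo error across the grids tested, and the reference duration
  makes explicit that the observed-scale value is a property of the
  sampling design, not of the population.

`CV_B`, the SD of unit effects on the latent scale, is reported alongside:
it is unaffected by sampling effort and is the comparable-across-studies
summary of between-unit variation.

**Predictor side.** `fit_error_in_variable()` treats the latent rate as a
predictor of a Gaussian outcome:
$y_i \sim \mathrm{Poisson}(\lambda_i t_i)$,
$\log\lambda_i \sim N(\mu, \sigma^2)$,
$w_i \sim N(a + b\lambda_i, \sigma_{res})$. The latent log-rate is
integrated out with 40-node Gauss–Hermite quadrature and the five
parameters maximised by BFGS; Wald intervals come from the numerical
Hessian. The lognormal latent family mirrors the GLMM (same closed loop);
a posterior-sampling backend was considered and not included — the
marginal likelihood is smooth and low-dimensional here, and the recovery
suite (slope within 15% at $n = 500$, nominal-ish interval coverage of a
null slope) is the contract either mechanism must meet. The naive
comparator — regressing the outcome on the observed rate $y/t$ — is
attenuated by approximately the biological proportion, which the tests
check against the analytic value.

**Interval side.** `fit_interval_gamma()` pools within-observation
intervals and fits the gamma by maximum likelihood: Newton iteration on
the shape with the digamma score, moment-based start, tolerance $10^{-8}$
on the shape. Degenerate (near-constant) intervals drive the shape
estimate to its cap ($10^8$) with a warning instead of a crash; fewer than
30 pooled intervals flags the fit as imprecise. Shape near 1 means no
evidence of a refractory period.

## Survey arithmetic

Published summaries arrive on many scales; `summarise_survey()`
standardises each estimate to the count scale before computing the
expected CV $\sqrt{\sigma_x^2 - \bar x}/\bar x$ and the biological
proportion:

* SE with sample size becomes SD via $SE\sqrt{N}$; range and/or IQR via
  the normal-theory estimators (half-width divided by
  $2\Phi^{-1}\!\big(\tfrac{n - 0.375}{n + 0.25}\big)$ for the range,
  $2\Phi^{-1}\!\big(\tfrac{0.75n - 0.125}{n + 0.25}\big)$ for the IQR,
  their average when both are available); the variant used is recorded on
  the result, since sources rarely state which statistic they report.
* Subgroup summaries pooled into one sample use the weighted mean and the
  exact pooled SD including the between-group mean spread (`pool_groups`),
  verified in the tests against concatenated samples constructed with
  exactly those moments.
* Per-hour rates are multiplied back by the observation period; per-chick
  rates are back-calculated for the mean only, the SD being unrecoverable
  — such estimates are flagged and excluded from CV summaries.
* Estimates whose variance does not exceed the mean are *underdispersed*:
  the expected CV is set to 0 and flagged, and these zeros are **included**
  in the medians (the convention for survey summaries of this kind); the
  flag count is reported so users can recompute without them.
* When one dataset feeds several analyses, the `uses` column weights a
  second set of medians; both weighted and unweighted are reported because
  no single weighting is canonical.

The transformation artefact is worth restating: presenting a 2-h study's
20 ± 7.5 counts as 10 ± 3.75 per hour makes the recoverable expected CV
0.2 instead of 0.3 (stochastic error over-subtracted), while presenting a
30-min study's 5 ± 2.7 as 10 ± 5.4 per hour yields 0.438 (under-
subtracted). `rescale_to_count()` exists to undo exactly this before any
CV is computed.

## Numerical and degenerate-input conventions

* All formula outputs are kept at full precision; rounding happens only
  when printing or when a comparison to a published, printed value is
  requested.
* `expected_cv()` treats an excess variance below $10^{-10}\bar x$ as
  underdispersed, so exact variance-equals-mean inputs are flagged rather
  than returning a floating-point sliver.
* Zero-rate, zero-duration, negative-CV, out-of-range-ICC and
  shape-below-1 parameters are rejected with invalid-parameter errors, not
  silently clamped.
* GLMM fits with fewer than 20 units or fewer than 2 observations per unit
  warn; non-converged fits refuse to produce ICC reports.
* Experiment cells record fit failures (`n_failed`) rather than dropping
  them: non-convergence at a low mean count is itself a finding about that
  design.

## Problem sizes in the test suite

The suite exercises the estimators at sizes chosen to keep Monte-Carlo
error well below the assertion bands while running in about a minute:
10,000-replicate count-law checks, $10^5$-draw moment oracles for the
generator, GLMM recovery at 500 units × 5 observations (mean count 20),
EIV recovery at 500 rows, and the estimator-comparison experiment at 100
replicates per cell over mean counts {5, 10, 20} with 50 units × 4
observations. Tolerances on stochastic assertions are 3× the Monte-Carlo
standard error at those sizes (computed in the tests, not hard-coded)
plus a small discretisation allowance.

## Known limitations

* Heterogeneity is lognormal by construction; heavy-tailed or multimodal
  rate distributions are untested territory for the recovery guarantees.
* The refractory simulator is an ordinary renewal process; equilibrium
  start would matter for windows holding only a handful of events.
* The observed-scale ICC uses the lognormal-Poisson variance
  approximation; for very small reference mean counts (< 2) the
  approximation error is visible.
* Time-varying (inhomogeneous/Cox) rates, clustered processes, multi-type
  events, and compound measures (e.g. food amount per visit) are out of
  scope; so is heritability estimation, though `CV_B` is the natural
  bridge to it.
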