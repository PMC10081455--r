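# countproc

Behavioural rates are usually measured by counting events — feeding visits,
copulations, aggressive interactions — within a short observation window.
The count `y` over a window of length `t` is then treated as a proxy for a
latent rate `λ`. Describing the events as a Poisson point process makes the
cost of that shortcut explicit: even with a perfectly constant rate,
`y ~ Poisson(λt)`, so the counts carry *stochastic error* with variance
equal to their mean. By the law of total variance, across observations

    σ²_y = σ²_stoc + σ²_λt = λ̄t + (λ̄t · CV_exp)²

where `CV_exp` is the coefficient of variation of the expected rates (the
biological signal) and `λ̄t` is the mean number of observed events. Any
variance-standardised effect size computed from raw counts — repeatability
(ICC), R², heritability — is therefore attenuated by the factor

    m · CV²_exp / (1 + m · CV²_exp),      m = λ̄t

the proportion of observed variance that is biological. With a refractory
period (gamma-renewal intervals with shape `α > 1`) the stochastic variance
becomes `m/α` and the factor generalises to `α m CV² / (1 + α m CV²)`.

`countproc` is for behavioural and evolutionary ecologists who want to
quantify, predict, and remove this attenuation. It provides:

* **Simulators** — homogeneous Poisson and gamma-renewal (refractory) event
  series, and whole multi-unit studies with lognormal rate heterogeneity
  split between unit identity and observation (`simulate_poisson_events`,
  `simulate_gamma_renewal`, `simulate_study`), plus a gamma maximum-
  likelihood fit to interval lengths (`fit_interval_gamma`) whose mode
  estimates the refractory period.
* **Variance calculus** — `decompose_variance`, `expected_cv`,
  `biological_proportion`, `attenuate_icc`, `observed_cv`, and a sampling
  planner `plan_sampling` that returns the mean events per observation
  needed for a target biological proportion.
* **Survey arithmetic** — pooling subgroup summaries (`pool_groups`),
  SD recovery from SE or range/IQR (`sd_from_se`, `sd_from_range`),
  rate↔count rescaling (`rescale_to_count`, `unscale_per_chick`), and
  `summarise_survey` for whole tables of published estimates.
* **Corrected estimators** — Poisson-lognormal GLMM with an
  observation-level random effect and log-duration offset
  (`fit_count_glmm`), ICCs on latent / expected / observed scales plus
  `CV_B` (`icc_report`), the naive Gaussian comparator (`fit_naive_lmm`),
  and an errors-in-variables regression for counts used as predictors
  (`fit_error_in_variable`).
* **Experiments** — `run_bias_experiment`, `naive_curve`,
  `underdispersion_incidence` for bias/precision studies over grids of
  sampling effort.

## Worked example

A population with mean rate 10 events/hour, rate SD 3 (expected CV 0.3),
half of the rate variance due to consistent unit differences (expected-scale
ICC 0.5), observed for 2 hours:

```r
library(countproc)
decompose_variance(20, 0.3)
#> Count variance decomposition (mean 20 events, alpha = 1)
#>   stochastic variance : 20 (CV 0.224)
#>   expected-rate variance: 36 (CV 0.3)
#>   observed: variance 56, SD 7.483, CV 0.374
#>   proportion biological: 0.6429
```

So such a study sees 20 ± 7.5 events per observation, and only 64% of that
variance is biological. A naive Gaussian analysis can therefore estimate a
repeatability of at most 0.64, and with a true ICC of 0.5 it reports:

```r
attenuate_icc(0.5, c(20, 10, 5), 0.3)   # 2 h, 1 h, 30 min windows
#> [1] 0.3214286 0.2368421 0.1551724
```

— the same population yields 0.32, 0.24 or 0.16 depending purely on
sampling effort. Simulating that study and fitting both analyses:

```r
tab <- simulate_study(10, cv_exp = 0.3, icc_exp = 0.5, n_units = 200,
                      obs_per_unit = 5, duration = 2, seed = 1)
fit_naive_lmm(tab)$icc_observed          # attenuated, as predicted
#> [1] 0.2664981
icc_report(fit_count_glmm(tab), reference_duration = 2)
#> Repeatability (ICC) report
#>   latent scale   : 0.427
#>   expected scale : 0.4168  (stochastic error excluded)
#>   observed scale : 0.2701  (at 2 h, mean count 20.1)
#>   CV_B (latent-scale between-unit SD): 0.1887
```

The Poisson-lognormal GLMM recovers the expected-scale ICC near its true
0.5 (here 0.42 from 200 units; the sampling spread shrinks with study
size), while both observed-scale numbers sit on the analytic attenuation
curve. To design a study where 90% of observed variance is biological:

```r
plan_sampling(0.3, 0.9)
#> [1] 100
```

i.e. aim for a mean of 100 observed events per observation (10 hours at
this rate). A survey table of published summaries (a small synthetic
example ships with the package) is standardised and summarised with:

```r
path <- system.file("extdata", "synthetic_survey_example.csv",
                    package = "countproc")
summarise_survey(read_survey_table(path))
#> Survey of 8 published estimates (7 with usable SD, 2 underdispersed -> CV 0)
#>   median mean count          : 9.9
#>   median expected CV         : 0.402 (range 0-0.889)
#>   median biological proportion: 0.702
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "countproc.R", package = "countproc")` with subcommands
`simulate | decompose | plan | fit-glmm | fit-intervals | survey`.

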