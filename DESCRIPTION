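Package: countproc
Title: Poisson-Process Models and Corrected Effect Sizes for Behavioural Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing behaviours quantified by counting events in a
    fixed observation window (e.g. parental provisioning visits). Simulates
    event series under homogeneous Poisson and gamma-renewal (refractory)
    point processes with between-observation rate heterogeneity; provides the
    closed-form decomposition of observed count variance into Poisson
    stochastic error and biological (expected-rate) variance, with the
    resulting attenuation of ICC, repeatability and R-squared; standardises
    published count summaries back to the count scale and recovers the
    expected coefficient of variation; fits Poisson-lognormal mixed models
    with observation-level random effects and log-exposure offsets, and
    errors-in-variables regressions that treat the latent event rate as a
    predictor; and plans sampling effort (mean events per observation) needed
    to reach a target proportion of biological variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    pracma,
    stats,
    utils
Suggests:
    fitdistrplus,
    glmmTMB,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
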