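Package: disjunctDDM
Title: Drift-Diffusion Decomposition of the Disjunction Effect in the
    Prisoner's Dilemma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to decompose the disjunction effect in the one-shot
    Prisoner's Dilemma game into drift-diffusion model (DDM) components.
    Provides Wiener first-passage-time densities, closed-form choice
    probabilities, response-time quantiles and a seeded Euler-Maruyama
    trial simulator; per-subject quantile-probability chi-square
    estimation of condition-specific drift, boundary and starting-point
    parameters with a shared non-decision time, minimized by differential
    evolution; a synthetic-experiment generator (payoff matrices with the
    canonical T > R > P > S ordering, social-value-orientation
    heterogeneous cohorts, trial tables, quality-control filters); SVO
    Slider angle computation and mean +/- SD trait grouping; defection
    rates, the disjunction effect size (EOD), repeated-measures ANOVA
    with Greenhouse-Geisser correction and Bonferroni post hoc tests;
    PMVD/LMG relative-importance decomposition of defection-rate
    variation onto DDM parameter variations; and quadratic
    social-value-orientation regressions with bias-corrected accelerated
    (BCa) bootstrap mediation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
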