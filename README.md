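# disjunctDDM

Drift-diffusion decomposition of the disjunction effect in the
Prisoner's Dilemma.

## What this package is for

In one-shot Prisoner's Dilemma experiments, people defect less when
they do not know the opponent's move (condition U) than when told the
opponent defected (D) or cooperated (C) — the *disjunction effect*, a
violation of the sure-thing principle.  Its per-subject size is

```
EOD = (p(Defect|D) + p(Defect|C)) / 2 − p(Defect|U)
```

This package is for cognitive modellers who want to attribute that
behavioral effect to latent decision components.  It fits the drift
diffusion model (DDM) to each subject's choices and response times per
condition: evidence `X(t)` accumulates between absorbing boundaries 0
(cooperate) and `a` (defect), starting at `a(1−z)` with drift `v` and
noise scale `s`; RT is the first-passage time plus a non-decision time
`t_er` shared across conditions.  `v` is read as deliberative
preference strength for defection, `z` as intuitive prosocial
(cooperation-ward) bias.  Around this core it provides:

* Wiener first-passage numerics: closed-form defection probabilities,
  small/large-time series densities, CDFs, RT quantiles, and a seeded
  Euler–Maruyama trial simulator (`choice_probability`, `fpt_density`,
  `fpt_cdf`, `rt_quantiles`, `simulate_trials`);
* per-subject quantile-probability chi-square estimation of `(v, a, z)`
  per condition with one shared `t_er`, minimized by differential
  evolution plus a simplex polish (`compute_qp`, `qp_chisq`,
  `fit_subject`, `fit_experiment`, `fit_report`);
* a synthetic-experiment generator emulating the study design — 150
  jittered payoff matrices under `T > R > P > S`, SVO-heterogeneous
  cohorts with condition-dependent true parameters, trial tables, QC
  exclusion filters (`generate_payoff_matrices`, `generate_population`,
  `generate_experiment`, `apply_qc_filters`);
* SVO Slider angle computation and mean ± 1 SD trait grouping
  (`svo_angle`, `classify_svo`);
* behavioral statistics: defection rates, EOD, repeated-measures ANOVA
  with Greenhouse–Geisser correction and partial eta-squared,
  Bonferroni post hoc tests, logit-bias robustness (`defection_rates`,
  `eod`, `rm_anova`, `bonferroni_pairwise`, `logit_transform`);
* PMVD/LMG relative-importance decomposition of defection-rate
  variation onto DDM parameter variations (`variation_regression`,
  `pmvd_shares`, `lmg_shares`);
* quadratic SVO regressions and BCa-bootstrap mediation of the
  quadratic trait effect through bias variation (`quad_regression`,
  `mediate_quadratic`, `bca_interval`);
* a seeded end-to-end pipeline with CSV/JSON outputs and a markdown
  report (`run_pipeline`), plus a thin CLI at
  `inst/cli/disjunct_ddm.R` with subcommands
  `simulate`/`qc`/`fit`/`analyze`/`report`/`all`.

## Worked example

```r
library(disjunctDDM)

p <- ddm_params(v = 1, a = 1.5, z = 0.4, t_er = 0.3)
p
#> DDM parameters: v = 1, a = 1.5, z = 0.4, t_er = 0.3 s (s = 1)
#>   start = a*(1-z) = 0.9; P(defect) = 0.8784

sim <- simulate_trials(p, 1e5, dt = 1e-4, seed = 42)
mean(sim$choice == "defect")
#> [1] 0.8777

rt_quantiles(p, c(0.1, 0.3, 0.5, 0.7, 0.9), boundary = "defect")
#> [1] 0.3936400 0.4763146 0.5850121 0.7616908 1.1637494
```

The simulated defect fraction sits within Monte-Carlo error of the
closed-form 0.8784, and the model's median defect RT (0.585 s) matches
the simulated one (0.584 s).  A miniature end-to-end run (small cohort,
light optimizer, so individual estimates are noisy):

```r
cfg <- pipeline_config(seed = 11, n_subjects = 20, n_trials_per_condition = 30,
                       de = de_control(pop_factor = 6, maxiter = 60),
                       n_boot = 1000, dt_experiment = 1e-3)
res <- run_pipeline(cfg, "pipeline_out")
res$results$rates$mean_p_def
#> $p_def_U  [1] 0.6116667
#> $p_def_D  [1] 0.7683333
#> $p_def_C  [1] 0.6283333

res$results$rates$mean_eod
#> [1] 0.08666667
res$results$anova$bias$partial_eta_sq
#> [1] 0.1744919
```

Defection is most frequent when the opponent is known to defect and
the mean EOD is positive — the generator's encoded disjunction-effect
structure, recovered through the full simulate → QC → fit → analyze
chain.  `pipeline_out/report.md` contains the rate/EOD summary, the
three parameter ANOVAs, the variation decomposition with PMVD shares,
the quadratic SVO regressions, and the mediation table.

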