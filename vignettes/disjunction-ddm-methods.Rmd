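---
title: "Decomposing the disjunction effect with a drift diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing the disjunction effect with a drift diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

In the one-shot Prisoner's Dilemma, people cooperate more when they do
*not* know the opponent's move (condition U) than when they are told the
opponent defected (D) or cooperated (C) — the disjunction effect, a
violation of the sure-thing principle.  Its size is summarized per
subject by

$$\mathrm{EOD} = \tfrac{1}{2}\,[p(\mathrm{Defect}\mid D) +
p(\mathrm{Defect}\mid C)] - p(\mathrm{Defect}\mid U).$$

`disjunctDDM` decomposes this behavioral effect into latent
decision-process components using the drift diffusion model (DDM): noisy
evidence $X(t)$ accumulates between two absorbing boundaries, 0
(cooperate) and $a$ (defect), starting from $a(1-z)$, with drift $v$
toward defection and noise scale $s$.  The response time is the
first-passage time plus a non-decision time $t_{er}$.  In this social
context, $v$ is read as deliberative preference strength for defection
and $z$ as the intuitive prosocial (cooperation-ward) bias: raising $z$
moves the start point away from the defection boundary and strictly
lowers the defection probability.

A note on the bias convention, which was a genuinely open design choice:
one also finds the opposite convention (start at $z \cdot a$, large $z$
meaning defection-prone) in the DDM literature.  We fix start $= a(1-z)$
with $z$ cooperation-ward because it makes all downstream signs
coherent: the prosocial-trait/bias correlation is positive, the bias is
lowest under D, and bias variation relates negatively to
defection-rate variation.  All code, documentation and outputs use this
single convention.

## Core numerics

Closed-form absorption probability:
$P(\mathrm{defect}) = \dfrac{1 - e^{-2va(1-z)/s^2}}{1 - e^{-2va/s^2}}$,
with the driftless limit $1 - z$ (evaluated through `expm1` for
stability).  First-passage densities use the classic small-time and
large-time series pair; for each evaluation the expansion needing fewer
terms at a target truncation error of $10^{-7}$ (on the scaled-density
scale) is chosen, so the crossover adapts to $t/a^2$.  The CDF uses the
analytically integrated large-time series — an exponential tail sum,
truncated when the term envelope falls below $10^{-13}$ — and partial
sums are clamped into $[0, P(\text{boundary})]$.  Within the fitting
bounds ($|v| \le 5$, $a \le 4$, $z \in [0.05, 0.95]$, $s = 1$), the
exponential prefactor is at most $e^{19}$, so worst-case cancellation in
the tail sum leaves absolute errors near $10^{-11}$.

The trial simulator is Euler–Maruyama with Gaussian increments of SD
$s\sqrt{dt}$ (default $dt = 10^{-4}$ s), augmented with the standard
Brownian-bridge mid-step crossing test: a step that ends inside the
boundaries may still have crossed one in between, with probability
$\exp(-2 d_1 d_2 / (s^2 dt))$ for boundary distances $d_1$ (before)
and $d_2$ (after); ignoring this biases absorption probabilities by
$O(\sqrt{dt})$, which is detectable against the closed form already at
$n = 10^5$ trials for small boundary separations.  With the bridge
test the simulator agrees with the closed-form absorption
probabilities within Monte-Carlo noise on a 27-point parameter grid at
$dt = 10^{-4}$, and spot checks show the same at the coarser
$dt = 10^{-3}$ used by the cohort-scale experiment generator.  The simulator uses its own seeded RNG stream
(xoshiro256++ with a polar Box–Muller transform), so results are
reproducible from the `seed` argument alone and independent of R's
global RNG.

The noise scale is fixed at $s = 1$.  The alternative $s = 0.1$
convention is a pure rescaling of $v$ and $a$; `s` is exposed as an
argument everywhere for users who prefer it.

## Quantile-probability estimation

Each subject is summarized per (condition, response) by the response
proportion and the RT quantiles at probabilities 0.1, 0.3, 0.5, 0.7,
0.9 (`compute_qp`).  The fit statistic (`qp_chisq`) cuts each
response's observed RTs at the model-predicted quantiles, giving six
bins with expected masses (0.1, 0.2, 0.2, 0.2, 0.2, 0.1) of the
predicted response probability, plus one response-proportion cell per
response; cells whose response has fewer than five observed trials
contribute only the proportion cell.  Expected counts are floored at
$10^{-10}$.

`fit_subject` minimizes this statistic over ten parameters — $(v, a,
z)$ for each of U, D, C plus a single shared $t_{er}$ — with elitist
rand/1/bin differential evolution (population $15 \times$ dimension,
$F = 0.8$, $CR = 0.9$, at most 300 generations, relative spread
tolerance $10^{-8}$; all configurable), followed by a deterministic
Nelder–Mead polish from the best member.  The polish matters: at 50
trials per condition the DE alone routinely stops 20–40% above the
local optimum, adding avoidable estimation noise.  Bounds default to
$v \in [-5, 5]$, $a \in [0.3, 4]$, $z \in [0.05, 0.95]$,
$t_{er} \in [0.1, \min \mathrm{RT} - 10^{-3}]$.  A condition with zero
response variability widens the $z$ bounds to $[0.01, 0.99]$ with a
warning instead of failing.  Subjects are fit independently — the
design's explicit choice; hierarchical pooling is out of scope.

Inside the optimizer, predicted quantiles are obtained by evaluating
the conditional CDF on a 96-point log-spaced time grid
($10^{-3}$–$30$ s) with linear interpolation; the user-facing
`rt_quantiles` uses full bisection instead.  The interpolation error
(a few milliseconds) is far below the sampling noise of 50-trial
quantiles.

At the study's budget (50 trials/condition), parameter uncertainty is
dominated by sampling noise, not the optimizer: with 20 generator-default
subjects the fitted prosocial bias rank-correlates with truth above 0.8
(pooling conditions) with median absolute error well under 0.08, while
drift is recovered more noisily (median absolute error about 0.2), as
expected for quantile-based objectives.

## The synthetic cohort generator

No raw subject data are distributed with the study, so the generator is
the package's substrate for testing the full chain.  It emulates the
published design and summary structure:

* **Payoff matrices** — a prototype with cells (T, R, P, S) = (59, 40,
  28, 10), jittered by independent uniform integers in $[-10, 10]$ per
  cell, rejecting draws violating $T > R > P > S$, 150 matrices split
  at random into three 50-matrix condition sets.  The prototype is a
  reconstruction chosen so the jittered pool reproduces the published
  mean gaps ($T{-}R \approx 19$, $R{-}P \approx 12$, $P{-}S \approx
  18$); the original prototype cells were not published.  The shipped
  `inst/extdata/payoffs_synthetic.csv` is one seeded draw of this
  generator and is labelled synthetic accordingly.
* **Subjects** — SVO angles $\sim$ Normal(20.86°, 8°); the SD is not
  printed in the study and 8° is a typical Slider-cohort value that
  reproduces tail groups of about 12 of 72 under the mean ± 1 SD rule.
  Trait groups are cut on the *realized* sample.
* **Condition-dependent parameters** — group means of the bias shifts
  are set to the published group-level variation means
  ($\Delta z_{U \to D}$: −0.060 proself, −0.147 intermediate, −0.050
  prosocial; $\Delta z_{U \to C}$: +0.097, −0.012, −0.017), with the
  published SDs.  Baseline bias rises with trait group (0.42, 0.50,
  0.58), giving the positive trait–bias association.  Drift is lower
  under U ($v_U = 0.40$, shifts $+0.15$ under D and C), boundary
  separation ($a = 1.5$) and non-decision time ($t_{er} = 0.35$ s) are
  condition-constant per subject.  These level values are *not*
  published estimates — only the shift means/SDs are — and were chosen
  once so that analytic defection probabilities land near the published
  condition means (64%, 80%, 70% for U, D, C).
* **QC filters** — modal-response share ≥ 0.98 over all trials, or
  more than 10% of RTs faster than 0.2 s, excludes a subject.  The
  study names both rules but no thresholds; these defaults are ours.

What the generator does **not** emulate: sequential/carryover effects
across trials, key-mapping or motor biases, payoff-matrix-specific
behavior (matrix ids are bookkeeping only), within-subject parameter
drift, and RT contamination (guesses, lapses).  Passing tests therefore
show that the estimation and analysis chain recovers the structure this
generative model encodes — not that real data are free of those
complications.

## Statistical layer

The repeated-measures ANOVA is computed from the explicit
within-subject SS decomposition; partial $\eta^2 =
SS_\text{effect}/(SS_\text{effect}+SS_\text{error})$.  The
Greenhouse–Geisser $\varepsilon$ comes from the eigenvalues of the
orthonormally contrasted covariance of condition scores, and in the
default `auto` mode the correction is applied when a Mauchly sphericity
check rejects at 0.05 (the study reports corrected df for rates and
uncorrected df for the DDM parameters without stating a rule; `auto`
reproduces that mix, and `on`/`off` override it).  Pairwise
comparisons are paired t tests with Bonferroni-multiplied p values.
The bias ANOVA is rerun on logit-transformed $z$ as a robustness
check, with boundary values clamped at $10^{-6}$.

The variation decomposition regresses each subject's defection-rate
variation on the three corresponding parameter variations
(standardized OLS), and attributes explained variance by PMVD:
orderings of the three predictors are enumerated exactly (6
permutations) and weighted proportionally to
$\prod_{i=1}^{p-1} [R^2_{\text{full}} - R^2(r_1,\dots,r_i)]^{-1}$,
each ordering contributing its sequential $R^2$ increments.  This
weighting gives PMVD its exclusion property — predictors with zero
population coefficients receive vanishing shares — which the tests
verify at $n = 10^4$, alongside exact agreement with a brute-force
enumeration oracle.  LMG (the unweighted average) is provided as a
diagnostic comparator.  Orderings with near-zero remaining variance
are floored at $10^{-12}$ before inversion; such fits are effectively
saturated and the weights concentrate correctly in the limit.

SVO regressions standardize the angle before squaring, so the
quadratic coefficient is curvature per squared SD of trait.  The
mediation analysis treats the squared standardized SVO as the
treatment with the linear term as covariate in both the mediator model
($\Delta z \sim s + s^2$) and the outcome model
($\Delta p \sim s + s^2 + \Delta z$); effects are the OLS
product-of-coefficients decomposition, for which direct + indirect =
total is an exact identity.  Confidence intervals are BCa over
nonparametric subject resampling (default 5000 draws): bias
correction from the tie-aware bootstrap CDF at the point estimate,
acceleration from jackknife skewness, with a percentile fallback for
degenerate bootstrap distributions.  One printed table header uses the
reversed sign ($z_U - z_C$) for the C-block bias variation while the
text uses $z_C - z_U$; the analysis bundle reports both signs
explicitly so either convention can be read off.

## Problem sizes and reproducibility

Every stochastic stage takes an explicit seed, and cohort-level seeds
are derived deterministically from one master seed, so pipeline runs
are byte-reproducible.  The test suite and the acceptance script use
deliberately sized problems: simulator validation at $10^5$ trials per
grid point ($dt = 10^{-4}$), recovery at 20 subjects × 150 trials,
the qualitative-pattern check over 100 seeded cohorts of 72 subjects
(trial simulation at $dt = 10^{-3}$, where the discretization bias is
negligible relative to trial noise), and one fitted cohort per run
(the acceptance script fits all 72 subjects; the in-suite fitted check
uses a 24-subject cohort).  Fitting uses a slightly lighter optimizer
configuration (population $10\times$ dimension, 150 generations, plus
the polish) whose solutions match the default configuration to well
within sampling noise.

## Known limitations

* Inter-trial variability parameters ($s_v$, $s_z$, $s_t$), collapsing
  bounds, and hierarchical (e.g. HDDM-style) pooling are out of scope.
* The non-decision time is a single shared constant per subject; no
  nonparametric non-decision distribution is estimated.
* The QP chi-square uses fixed quantile probabilities; with very few
  trials per response the statistic degrades to proportion cells only.
* PMVD is enumerated exactly only up to six predictors (three are used
  here).
* The generator's group-step structure implies the inverted-U trait
  relationships; it cannot discriminate alternative smooth nonlinear
  forms (splines, exponentials), which the study itself leaves to
  future work.
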