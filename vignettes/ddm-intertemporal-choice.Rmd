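---
title: "Hierarchical drift diffusion modelling of intertemporal choice"
author: "itcddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical drift diffusion modelling of intertemporal choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itcddm)
```

# The scientific problem

In an intertemporal choice task a decision maker repeatedly chooses between
a smaller-sooner (SS) and a larger-later (LL) monetary reward. Classical
analyses compress each person's behavior into a single discount rate, which
hides *how* the decision is reached. `itcddm` decomposes each decision with
a two-boundary drift diffusion model (DDM): noisy evidence accumulates from
a starting point $\zeta$ between a lower boundary (choose SS) and an upper
boundary at separation $a$ (choose LL); the mean accumulation rate is the
drift $v$, and the response time is the boundary-hitting time plus a
non-decision time $\tau$. Pharmacological conditions (e.g. a dopamine
D2-receptor antagonist given within-subject, or a D1 agonist given
between-subject in several doses) can then act on *separate* components:
the weighting of reward magnitudes and delays during accumulation, and the
pre-decisional starting bias.

# The model

Each trial contributes its attributes as z-scored differences
($M_{diff}$ = LL $-$ SS magnitude, $D_{diff}$ = LL $-$ SS delay; z-scoring
is pooled over the study's retained trials so coefficient sizes are
comparable). The winning variant (`ddm1`) maps them onto the diffusion
parameters as

$$v' = \beta_1 M_{diff} + \beta_2 (Drug \times M_{diff})
     + \beta_3 D_{diff} + \beta_4 (Drug \times D_{diff}),$$
$$v = v_{max} \left( \frac{2}{1 + e^{-v'}} - 1 \right)
    = v_{max} \tanh(v'/2),$$
$$\zeta = \beta_7 + \beta_8\, Drug + \beta_9 D_{diff}
        + \beta_{10} (Drug \times D_{diff}),$$
$$a = \beta_{11} + \beta_{12}\, Drug, \qquad
  \tau = \beta_{13} + \beta_{14}\, Drug,$$

with the drug code 0/1 in the within-subject design. The sigmoidal link
bounds the drift at $\pm v_{max}$ (itself drug-dependent), which fits
observed behavior better than a linear link. Five alternatives bracket this
specification: a fixed bias $\zeta = 0.5$ (`ddm2`); an attribute-free drift
(`ddm3`, choices carried by the bias alone); the delay *sum* as the bias
covariate (`ddm4`, overall proximity instead of relative proximity); a
drift built from hyperbolically discounted values
$v' = LL_{mag}/(1 + k\,LL_{delay}) - SS_{mag}/(1 + k\,SS_{delay})$ on raw
attributes with a free non-negative discount weight (`ddm5`); and a
relative-starting-time model (`ddm6`) in which delay evidence starts
$\tau_{diff}$ seconds before magnitude evidence, giving a duration-weighted
effective drift that depends on the trial's decision time. `variant_matrix()`
prints the full inclusion table. Every parameter included in a variant
carries a drug effect.

Piecewise formulations of the relative-starting-time drift are easy to get
wrong (the branch conditions and weights are error-prone);
`drift_time_varying()` therefore implements the semantics directly — the
early attribute alone drives accumulation during the asynchrony window,
and the effective drift is the duration-weighted average — which reduces
to the usual special cases in its limits. Because the effective drift
conditions on the observed RT, `ddm6` is fit-only: the generator refuses it,
and its likelihood is the standard approximation inherited from the
relative-starting-time approach.

## Hierarchy, priors, estimation

Individual coefficients are normally distributed around group-level means
with one SD $\lambda$ per effect; group means have standard normal priors
and each $\lambda$ a Gamma(1, 1) prior (mean 1 — weakly informative on the
z-scored coefficient scale; both are `ddm_prior()` arguments). In the
between-subject design, separate group-level means are estimated per dose
group (contrasts via `contrast_conditions()`), with $\lambda$ shared across
groups — the minimal reading of "one $\lambda$ per effect" that also
stabilizes estimation at 30 participants per group.

The likelihood is the exact Wiener first-passage density (unit diffusion
coefficient; upper boundary = LL choice), computed in compiled code with
the dual small-time/large-time series and automatic truncation at an
absolute standardized error below $10^{-10}$. Sampling is blockwise
adaptive Metropolis-within-Gibbs: per participant, the drift, bias and
threshold/non-decision blocks are updated jointly with proposal covariances
learned during warmup (the drift block is strongly correlated — saturation
trades off against slope — and diagonal proposals mix visibly worse);
group means have conjugate Gibbs updates; each $\lambda$ takes a log-scale
random walk. Admissibility (positive $a$, $\tau$, $v_{max}$, non-negative
discount weight, every trial's bias inside (0.02, 0.98), $\tau$ below every
RT) is enforced by rejection, so coefficients keep the natural scale on
which results are reported. Identity-scale bias regression plus rejection
was chosen over a logistic link deliberately: a link would change the
coefficient scale.

Initialization places group means at 0 except where 0 is inadmissible:
the bias intercept starts at 0.5, $v_{max}$ at 1, the threshold intercept
at 2, the non-decision intercept at half the (participant's) minimum RT,
and the discount weight at 0.01; chains are jittered independently.
Convergence is summarized by rank-normalized split R-hat with the pass rule
max $\hat R < 1.01$; non-convergence warns but does not abort. Model
comparison uses DIC $= \bar D + p_D$, $p_D = \bar D - D(\bar\theta)$, with
$D(\bar\theta)$ evaluated at the posterior means of the individual-level
coefficients (the parameters that enter the likelihood).

Default desk-scale settings are 2 chains of 20,000 iterations (10,000
warmup, thinning 5); `full_scale = TRUE` restores the full-scale protocol
(2 × 500,000 / 450,000 / thin 5 within-subject; 2 × 100,000 / 50,000 /
thin 5 between-subject), which takes hours.

# Preprocessing

`trim_rts()` removes the 2.5% fastest and slowest trials by default. The
tails are taken from the pooled study RT distribution (a single global
rule; per-participant trimming at 20 trials per session would remove
fractional trials), with a `scope` option for per-participant
or per-session trimming. The quantile is the linear-interpolation sample
quantile and removal uses strict inequalities, so ties at the threshold are
retained — deterministic and conservative at small n. `standardize_attributes()`
z-scores the four attribute regressors pooled across participants and
sessions within a study (the two studies are standardized separately) and
records the affine transform so raw units can be recovered.

# What the synthetic generator emulates

`task_template("d2")` reproduces the within-subject design: 56 participants
× 2 sessions (placebo/amisulpride), 20 choices per session, SS 5–250
currency units at 0–30 days versus LL 15–300 units at 3–90 days, whole
units and whole days, with LL strictly larger and strictly later.
Attributes are sampled uniformly under those constraints; the empirical
task this template mirrors selected stimuli *adaptively* to maximize
information per trial, which the generator deliberately does not reproduce
— a consequence discussed below. `task_template("d1")`
reproduces the between-subject design: 120 participants in four dose
groups, 54 trials as the full factorial of SS magnitude (0–16 in steps of
2, immediate) × LL delay (six levels, 0–180 days; the LL is always 16
units), each combination once in random order. The delay levels within
0–180 days are the package's choice (0, 7, 30, 60, 90, 180) as the printed
description fixes only the range and the cell count.

`generate_dataset()` draws individual coefficients around a group-level
truth — by default the reference posterior means of the winning model
(`reference_coefs()`) — with heterogeneity SDs `reference_lambda()`, and
simulates choices and RTs through the exact first-passage sampler. The
heterogeneity defaults are the package's one-time choice: spread comparable
to the group-level effect sizes for drift weights, small absolute spread
for bounded parameters, such that essentially all simulated individuals
fall in the admissible region. Under the reference truth, simulated RTs
center around 4–6 s (threshold ≈ 4, non-decision time ≈ 1.5 s), so
trimming and predictive checks operate on realistic scales.

What generated data do *not* show: adaptively concentrated stimuli,
session-order or fatigue effects, within-person parameter drift, and
contaminant responses. Passing recovery tests on generated data therefore
demonstrates the estimator's internal consistency under the stated
hierarchy, not robustness to those real-data features.

# Diagnostics

`posterior_predictive_check()` regenerates every trial from the
individual-level posterior means (a draw-resolved mode exists when
individual draws are stored), bins trials into pooled sample-quantile
quintiles of the magnitude difference and, separately, of the delay
difference (stable tie-break on trial order; bin sizes differ by at most
one), and compares observed and simulated mean RTs per bin and condition.
The reported score is the mean squared difference between observed and
simulation-averaged bin means over all attribute × bin × condition cells —
the package's documented operationalization of the observed-vs-simulated
discrepancy; per-participant variants can be derived from the returned
long table.
`parameter_recovery()` simulates datasets from the fitted group-level
means, refits, and reports which group effects land back inside the
original 95% HDIs. `choice_probability_surface()` evaluates P(choose LL)
over the attribute plane for two coefficient sets via the closed-form
absorption probability (optionally by simulation) — the drug-minus-placebo
surface changes sign across the plane, the signature of opposing drift and
bias effects.

# Model-free companions

`fit_choice_mglm()` and `fit_rt_mglm()` are hierarchical Bayesian
regressions (logistic for LL/SS choice; linear for log RT with added
choice and magnitude-sum predictors) with participant random intercepts
and random slopes for every predictor, with weakly informative
Normal(0, 5) fixed-effect priors and half-Normal(0, 1) random-SD priors. `fit_discounting()` estimates the hyperbolic discount
rate and softmax inverse temperature per participant and session on the
log scale (priors: $\log k \sim N(-3, 2)$, $\log\beta \sim N(-1, 2)$,
overridable), and `bayesian_ttest()` provides the robust two-group t model
(Student-t likelihood, shared normality parameter with exponential-plus-one
prior) plus a paired variant on difference scores, the statistically
natural option for a within-subject comparison. These standard fits run on
JAGS via `rjags`; the DDM sampler itself is the package's own.

# Numerical choices and limitations

* **Density**: dual-series evaluation with truncation bounds guaranteeing
  absolute error $\le 10^{-10}$ on the standardized scale; acceptance
  checks verify mass conservation and closed-form absorption to $10^{-6}$
  on a 63-point grid.
* **Simulator**: boundary drawn from the exact absorption probability;
  hitting time by inversion of the numerically integrated conditional
  density (trapezoid step adapted to $\min(a^2 z(1-z), a/|v|)/800$, capped
  at 0.02 s). Draws sharing a parameter row share one integration sweep, so
  1000-fold predictive simulation is cheap. Agreement with an independent
  Euler–Maruyama simulation and with closed-form moments is part of the
  test suite.
* **Sampler sizes**: the test suite and acceptance script use desk-scale
  protocols — recovery at 20 participants × 2 × 100 trials with 2 × 20,000
  iterations, DIC discrimination at 12 × 2 × 40 with 2 × 3,000, predictive
  self-consistency at 10 × 2 × 60 with 2 × 4,000 — chosen as the smallest
  sizes at which the checked properties are stable.
* **Saturation identifiability**: with z-scored attributes and reference
  coefficients, many trials sit in the saturated region of the tanh link,
  where an increase in a drift *slope* (e.g. the drug × magnitude
  interaction) is nearly indistinguishable from a small increase in
  $v_{max}$. At desk scale with heterogeneous individuals this biases the
  drug-slope group means toward zero while their signs remain recoverable;
  at large n the maximum-likelihood solution recovers all coefficients.
  This is a property of the sigmoid-link model class, worth keeping in mind
  when interpreting small-sample drug interactions.
* **$\lambda$ funnel**: small heterogeneity SDs mix slowly under the
  centered parameterization (the usual funnel); the convergence flag
  reports this honestly. Group-level means, the quantities inference is
  based on, mix well in all tested regimes.
* **DDM-3's $v_{max}$** is retained to match the variant table but is
  unidentified there (the drift is identically zero); its posterior equals
  its prior.
* **Degenerate inputs**: empty datasets, zero-variance attributes,
  all-identical RTs, all-same choices and inadmissible coefficient sets
  are rejected or flagged with explicit messages rather than silently
  accepted.
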