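---
title: "Multilevel compositional analysis of daily 24-hour physical behavior"
author: "coda24"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel compositional analysis of daily 24-hour physical behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coda24)
```

## The problem

A day has a fixed budget: the minutes spent asleep, sedentary, standing, in
light physical activity (LPA) and in moderate-to-vigorous physical activity
(MVPA) always sum to 1440. Time-use data are therefore *compositional* --
only relative information is meaningful, and the parts are perfectly
collinear. Regressing a daily outcome (affect, cognition) on raw minutes is
ill-posed, and "spend more time in MVPA" is meaningless without saying which
behavior pays for it.

`coda24` implements the standard resolution for intensively sampled daily
data: express each day's five-part composition in isometric log-ratio (ilr)
pivot coordinates, split these into between-person and within-person levels,
fit a Bayesian multilevel Gaussian regression, and translate the posterior
into *time-reallocation* (substitution) effects -- the expected change in
the outcome when a fixed number of minutes moves from one behavior to
another.

## Geometry: pivot coordinates

For a composition $x = (x_1, \dots, x_D)$ taken in a chosen order, the pivot
coordinates are

$$ z_k = \sqrt{\tfrac{D-k}{D-k+1}}\,
   \ln \frac{x_{(k)}}{\left(\prod_{j>k} x_{(j)}\right)^{1/(D-k)}},
   \qquad k = 1, \dots, D-1 . $$

The first coordinate contrasts the pivot part against the geometric mean of
everything else, so with MVPA first, $z_1$ reads "MVPA relative to the
remaining behaviors". The map is a linear isometry of Aitchison geometry
(`ilr_pivot()`, `ilr_inverse()`), and pivot bases for different orderings
are related by an orthogonal matrix (`rotation_matrix()`). That last fact
carries the main reporting convenience: a model is fitted once, in one
basis, and coefficient draws are *rotated* into any other basis
(`rotate_basis()`, `summarize_fit(report_orders = ...)`) instead of
refitting. The package defaults to reporting MVPA-first and
sedentary-first coordinates; the two routes (rotation vs. independent
refit) agree within Monte-Carlo error, which the test suite checks
explicitly.

Coordinates $2, \dots, D-1$ depend on how the non-pivot parts are ordered;
`pivot_order()` fixes this to canonical label order after the pivot, and
nothing reported depends on it.

Zeros are rejected at closure (`close_composition()`) rather than imputed:
the intended day-level inclusion rules (sleep > 0 min, wear-time minimum)
make all five parts positive, so a zero signals an upstream problem. For
degenerate synthetic rows `offset_zero_parts()` can assign a small offset
(default 0.5 min) explicitly; it is never applied silently.

## Between/within decomposition

Repeated days per participant have two levels of variation. `decompose()`
computes each participant's compositional mean as the *geometric center* of
their days (equivalently: the arithmetic mean in ilr space) and splits each
day exactly:

$$ z_{ij} = \underbrace{\bar z_i}_{\text{between}} +
            \underbrace{(z_{ij} - \bar z_i)}_{\text{within}} . $$

The geometric (not arithmetic-in-minutes) center is what makes the
within-person deviations mean-zero in ilr space as an algebraic identity --
the decomposition has no residual, which the tests assert at $10^{-9}$ on a
full study-scale dataset. A day with a missing outcome still informs the
person's compositional mean; it is only dropped later from model rows.

The sample reference composition for substitution analyses
(`reference_composition()`) is the geometric center of the person means,
each participant weighted equally. Weighting by days instead (`pooled =
TRUE`) is provided because either reading of "the mean composition among
participants" is defensible; per-person equal weighting is the default.

## The model

For outcome $y_{ij}$ of participant $i$ on day $j$:

$$ y_{ij} \sim \mathcal N\!\big(\beta_0 + \beta_B^\top z^B_i
   + \beta_W^\top z^W_{ij} + \gamma^\top c_{ij}
   + u_{0i} + u_{Wi}^\top z^W_{ij},\ \sigma\big) $$

with covariates $c_{ij}$ = age, sex (male = 1), BMI, daily wear time, and
the previous-day lag outcome; a random intercept $u_{0i}$; and random
within-composition slopes $u_{Wi}$, jointly multivariate normal with a full
covariance. Continuous covariates are mean-centered, which shifts only the
intercept -- compositional coefficients and substitution differences are
unaffected.

The lag covariate uses *calendar adjacency*: day $j$'s lag is the outcome of
day $j-1$ only if that calendar day was observed. In the emulated workweek
design, weekends are break days, so Mondays have no lag and are dropped from
model rows (as is each participant's first day). The same adjacency rule
drives the prospective (next-day outcome) alignment in
`shift_outcome_next_day()`.

### Estimation and priors

Fitting is by Gibbs sampling via JAGS (`fit_mlcoda()`), with the `glm`
module's block samplers loaded -- without block updates, between-person
coefficients and the random intercept are nearly confounded and mix an
order of magnitude more slowly. Defaults are 4 chains of 2000 iterations
with 1000 warmup (4000 post-warmup draws), seeded per chain, and the same
seed reproduces draws exactly.

Priors are weakly informative, scaled by the outcome SD:

* coefficients: $\mathcal N(0, (10\,\mathrm{sd}(y))^2)$, intercept centered
  at $\bar y$;
* residual SD: half-Student-$t(3, 0, 2.5\,\mathrm{sd}(y))$;
* random-effect covariance: a *scaled inverse-Wishart* -- per-component
  half-$t(3, 0, 2.5\,\mathrm{sd}(y))$ scale factors around a
  Wishart$(I, K+1)$-correlated core.

The scaled form matters. A plain Wishart has a single scale and pools all
component SDs toward a common magnitude; here the random-intercept SD
(outcome units, often 5-10) and the random-slope SDs (outcome units per ilr
unit, often below 1) differ by an order of magnitude, and in recovery
experiments the plain Wishart visibly shrank the intercept SD, inflated the
slope SDs, and dragged the lag coefficient with it. The parameter-expanded
version gives each component its own half-$t$ scale while keeping a
full correlation structure.

### Convergence

`mcmc_diagnostics()` reports split-chain $\widehat R$ and a bulk effective
sample size (rank-normalized draws, split chains, per-chain effective sizes
summed). The convergence gate -- all $\widehat R < 1.05$ and ESS > 400 --
is applied to the population-level parameters (regression coefficients and
the residual SD); group-level SD diagnostics are computed and reported
alongside (`diagnostics$group_table`) but do not gate, following the
population/group vocabulary of the field's standard tooling.
Non-convergence is never an error: the fit is returned flagged and warned
about, and the pipeline surfaces it in its diagnostics table.

## Substitution analysis

For a reallocation of $m$ minutes to part $a$ from part $b$ at reference
composition $x^\*$, the posterior change per draw is

$$ \Delta y = \beta_\ell^\top\big(\mathrm{ilr}(x^\*_{a+m,\,b-m}) -
   \mathrm{ilr}(x^\*)\big), $$

with $\ell$ selecting the between- or within-level coefficients. Covariates
and random effects cancel exactly in this difference; the test suite keeps
that honest by recomputing every estimate as the difference of two full
linear predictions and requiring agreement to $10^{-10}$ per draw. At the
within level the reference day is an average day (zero within-deviation),
so the reallocated day's deviation is exactly the ilr difference.

Because the ilr transform is non-linear in minutes, adding 30 minutes to
MVPA from sedentary time and removing 30 minutes from MVPA into sedentary
time are *different* contrasts, not mirror images; `substitution_grid()`
therefore covers all ordered pairs (20 for five parts) at both levels over
a 1-60 minute grid, and `substitution_matrix()` renders the conventional
pairwise matrix (rows gain time, columns lose it) at a chosen duration,
30 minutes by default. Cells whose donor part would be exhausted are
flagged infeasible and reported as missing rather than dropped or errored.
Significance is defined throughout as the 95% equal-tailed credible
interval excluding zero; no multiplicity adjustment is applied, matching
standard practice for these posterior summaries.

## The synthetic-data generator

No participant-level dataset from such designs is publicly deposited, so
`simulate_emia()` generates the generative counterpart of the fitted model:
person-level ilr means from $\mathcal{MVN}(\mu_B, \Sigma_B)$, day-level
deviations from $\mathcal{MVN}(0, \Sigma_W)$, compositions through the
inverse ilr transform, and outcomes sequentially through the linear
predictor with random effects, lag-1 carry-over, and Gaussian noise.

Calibration targets are descriptive statistics typical of a workweek
ambulatory-assessment study of working adults (199 participants; mean
hours/day 7.95 sleep, 10.5 sedentary, 2.79 standing, 1.15 LPA, 1.35 MVPA;
outcome scales 0-100 with means ~65.7/56.3/60.9/88.6 and SDs ~12/12/13/9).
The covariances are built from interpretable per-part log-scale SDs
(`ilr_cov_from_log_sd()`), with total day-level variance split 60%
between-person / 40% within-person -- a ratio in the range reported for
daily behavior compositions. The frozen constants in `CODA24_CAL` were
produced once by fixed-point calibration at large $n$
(`analysis/00_calibrate_generator.R`), including a multiplicative center
correction that cancels the small Jensen/closure bias of log-normal parts.
Since raw target means sum to 23.74 h while compositions close to 24 h,
realized part means sit on the closure-normalized targets (at most 0.12 h
from the raw ones).

Design features emulated: a Monday-Friday monitoring calendar (weekend gaps
break lag chains), ~3 planned working weeks per participant, daily wear
time as 24 h minus a gamma non-wear draw (~20.7 ± 1.1 h), and day-level
validity failures (insufficient wear, no sleep, no walking detection) at
rates that exclude roughly a fifth of days -- so the *analyzed* days per
participant average ~11.8 (range within 3-22) after `filter_days()`.

Deliberately *not* emulated: prompt-level (momentary) sampling and its
sedentary-triggered scheme -- outcomes are generated directly at the daily
level; the ceiling effect of working-memory scores (all outcomes are
Gaussian); seasonal or weekday structure; informative missingness
(outcomes are missing completely at random at 5%/day). Passing tests on
this generator therefore demonstrate correctness of the *procedure* under
its own assumptions, not robustness to the skewness, floor/ceiling and
compliance artifacts of real ambulatory data.

## Recovery experiments and problem sizes

`recovery_experiment()` wraps the full pipeline (generate, filter,
decompose, design, fit) and scores compositional coefficients against the
generating truth: bias, RMSE, credible-interval coverage, and the rate at
which intervals exclude zero. The package's own calibration experiments use
20 replicates of 100 participants x 10 consecutive clean days with reduced
sampler settings (2 chains, 1000 post-warmup draws each): a strong first
within coordinate (3.65, a realistic energetic-arousal effect) is recovered
with mean bias around 5% and 19/20 coverage, while the seven null
coordinates flag at most 10% of the time against the nominal 5%. At this
replicate count the Monte-Carlo floor on the bias estimate is itself about
9% of the true value, so single-run bias percentages near 10% are expected
noise, not systematic error. The basis-rotation check uses two reduced fits
(50 participants x 8 days, 2 chains x 2000 post-warmup draws); the
convergence-gate check runs the default sampler settings on the bundled
20 x 6 fixture. These sizes keep the full test suite in single-digit
minutes on one core while leaving each check comfortable statistical
headroom.

## Known limitations

* Gaussian outcomes only; bounded 0-100 scales with ceiling effects (e.g.
  working-memory accuracy) are modelled as unbounded.
* Population-average substitution effects only -- person-specific slopes
  exist in the model but are not propagated into reallocation estimates.
* Pairwise reallocations only; one-to-many or proportional reallocation
  schemes are out of scope.
* The person mean is time-invariant; designs with systematic weekly drift
  would need a time-varying decomposition.
* Gibbs sampling with the scaled inverse-Wishart prior is not the same
  prior family as LKJ-based tooling; posterior SDs of weakly identified
  random-slope SDs can differ noticeably between the two, though fixed
  effects and substitution estimates are insensitive in our experiments.
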