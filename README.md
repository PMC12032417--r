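# coda24 — multilevel compositional analysis of daily 24-hour physical behavior

A day always contains 1440 minutes, split here into five behaviors: sleep
period, sedentary time, standing, light physical activity (LPA), and
moderate-to-vigorous physical activity (MVPA). Because the parts sum to a
constant, they carry only relative information and cannot be used as
ordinary regressors. `coda24` is for researchers analysing intensively
sampled daily data — accelerometer-derived behavior compositions paired
with daily outcomes such as affect ratings or mobile cognitive-task scores
— who want to ask: *what is the expected change in today's outcome when
30 minutes move from one behavior to another, within a person's own days
and between people?*

The package provides, as a tested library under an `analysis/` workflow:

* **Aitchison geometry** — closure, geometric centers, isometric log-ratio
  (ilr) pivot coordinates and their inverse, and orthogonal rotation
  between pivot bases (`close_composition`, `ilr_pivot`, `ilr_inverse`,
  `rotate_basis`, `geometric_center`).
* **Between/within-person decomposition** — each day's coordinates split
  exactly into the person's compositional mean and a mean-zero within-day
  deviation (`decompose`).
* **Bayesian multilevel model** — the daily outcome regressed on between-
  and within-person coordinates with covariates (age, sex, BMI, wear time,
  previous-day lag outcome), a random intercept and correlated random
  within-slopes, fitted by Gibbs sampling via JAGS with split-chain R̂ and
  bulk-ESS convergence gates (`model_spec`, `build_design`, `fit_mlcoda`,
  `summarize_fit`).
* **Substitution analysis** — posterior mean differences with 95% credible
  intervals for every pairwise reallocation of 1–60 minutes, at both
  levels, in both directions, plus 30-minute pairwise matrix views
  (`reallocate`, `substitution_estimate`, `substitution_grid`,
  `substitution_matrix`).
* **A calibrated synthetic-data generator** — the exact sampling
  counterpart of the model, emulating a workweek ambulatory-assessment
  study (199 participants, ~12 analyzed days each, day-level validity
  filters), for testing and parameter-recovery experiments
  (`generator_config`, `simulate_emia`, `recovery_experiment`).

## The model

With ilr pivot coordinates $z^B_i$ (person mean) and $z^W_{ij}$ (day
deviation),

```
y_ij ~ Normal( b0 + bB' zB_i + bW' zW_ij + g' c_ij + u0_i + uW_i' zW_ij , sigma )
```

where the first pivot coordinate under an MVPA-first ordering reads "MVPA
relative to the remaining behaviors". One model is fitted per outcome;
sedentary-first (or any other) summaries come from rotating the coefficient
draws by the orthogonal change-of-basis matrix, not from refitting.
Substitution effects are `bL' (ilr(reallocated) − ilr(reference))` per
posterior draw, with the reference composition the geometric center of the
participants' means. See `vignettes/multilevel-coda-24h.Rmd` for
assumptions, priors, and design choices.

## Worked example

```r
library(coda24)

d    <- read_behavior_csv(system.file("extdata", "ema_days_synthetic_small.csv",
                                      package = "coda24"))
filt <- filter_days(d)                      # wear/sleep/walk + min-days rules
dec  <- decompose(filt$data, order = pivot_order("mvpa"))
spec <- model_spec("valence", seed = 1)     # 4 chains x 2000 iter / 1000 warmup
fit  <- fit_mlcoda(build_design(dec, spec), spec)
fit$diagnostics$converged
#> [1] TRUE

summ <- summarize_fit(fit, report_orders = list(pivot_order("mvpa"),
                                                pivot_order("sedentary")))
subset(summ, coordinate == 1)
#>         parameter   level     pivot coordinate   mean lower upper significant
#> 1       b_mvpa_z1 between      mvpa          1  -0.74   -24    21       FALSE
#> 5       w_mvpa_z1  within      mvpa          1   0.29   -13    14       FALSE
#> 9  b_sedentary_z1 between sedentary          1 -14.18   -55    24       FALSE
#> 13 w_sedentary_z1  within sedentary          1   7.60   -13    28       FALSE

base <- reference_composition(filt$data)
round(base, 1)
#>     sleep sedentary  standing       lpa      mvpa
#>     477.4     635.2     178.0      66.2      83.1

substitution_estimate(fit, base, "mvpa", "sedentary", 30, "within")
#>    level   to      from minutes  mean lower upper significant feasible
#> 1 within mvpa sedentary      30 -0.25  -4.3   3.8       FALSE     TRUE
```

Each row of the coefficient table is a posterior mean with a 95%
equal-tailed credible interval for one first pivot coordinate — e.g.
`w_mvpa_z1` is the within-person association of "MVPA vs. the remaining
behaviors" with same-day valence, in outcome units per ilr unit. The
substitution row says that, on this small 20-participant fixture, moving
30 minutes from sedentary time into MVPA on a given day shifts expected
valence by −0.25 points with an interval spanning zero — intervals this
wide are what 120 days of data buy; the `analysis/` scripts run the same
pipeline at full study scale, where the generating effects are recovered.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the full study-scale analysis
on synthetic data, writing tables under `results/`:

* `00_calibrate_generator.R` — recompute/verify the generator's frozen
  calibration constants.
* `01_simulate.R` — generate the 199-participant cohort, apply day filters,
  write descriptives.
* `02_fit_models.R` — fit all outcomes, concurrent and prospective, report
  coefficients in MVPA-first and sedentary-first bases, write substitution
  grids (~15 min).
* `03_substitution_curves.R` — 1–60 min duration-response summaries and the
  reallocations whose intervals exclude zero.
* `04_recovery.R` — parameter-recovery and false-positive-rate experiments.

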