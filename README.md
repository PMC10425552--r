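# bitecurve

Cumulative intake curve models for bite-level meal data.

Within a single eating episode, the total grams consumed form a
decelerating, s-shaped *cumulative intake curve* whose shape carries the
dynamics of eating — initial rate, deceleration, satiation. Laboratory
devices (the Universal Eating Monitor, drinkometers) measure this curve by
continuously weighing the meal, but their protocols are hard to use with
children and with multi-item meals. Video-coded meals provide precise
*bite timings* but only an *average* bite size. `bitecurve` is for
researchers in ingestive behavior who want to characterize cumulative
intake curves from such bite-level records — and to know how much they can
trust the recovered parameters.

The package provides:

* **Two models of cumulative intake.** The quadratic model
  `E(t) = a t² + b t + c` (linear coefficient = eating rate, quadratic
  coefficient = change of eating rate, `a < 0` for satiation) and the
  logistic-ODE (LODE) model `dE/dt = (θ + rE)(1 − E/E_max)` with closed
  form `E(t) = (e^{kt} − 1)/(e^{kt}/E_max + r/θ)`, `k = r + θ/E_max`:
  initial eating rate θ (g/min), doubling rate r (1/min), asymptotic meal
  size E_max (g). Forward evaluation, exact inversion (bite timing from
  intake), and feasibility classification of predicted bites — the
  quadratic's inverted-U can predict non-feasible bites, the LODE curve
  cannot.
* **Maximum-likelihood fitting with data-driven profile-likelihood 95%
  confidence intervals** (`fit_model()`, `profile_cis()`).
* **A synthetic generator of child meal microstructure** (bite counts,
  totals, durations; truncated-logistic bite timings) and a
  **three-condition simulator**: constant bite (no noise), variable bite
  (process noise on bite sizes, as with continuous weighing), and bite
  measurement error (average bite size + jittered timings, as with video
  coding).
* **A parameter-recovery battery**: CI coverage, estimate
  distinguishability, a median-scaled Goodness of Fit Index, and
  curve-prediction error (RMSE and pseudo-R² in both the intake and the
  timing direction), with Fisher-exact and Mann–Whitney comparison
  statistics across models and conditions.

## A worked example

Simulate one video-coded-style meal (30 bites, 300 g, true θ = 30 g/min,
r = 0.15/min, asymptote 330 g), fit the LODE model, and profile the
intervals:

```r
library(bitecurve)
p <- lode_params(theta = 30, r = 0.15, emax = 330)
meal <- simulate_measurement_error(p, n_bites = 30, total_intake = 300,
                                   seed = 4)
fit <- profile_cis(fit_model(meal$bites, "lode", emax = 330), meal$bites)
print(fit)
#> lode model fit (n = 30 bites): logLik = -62.916, sigma = 2.887 g
#> LODE intake model: theta = 30.19 g/min, r = 0.1488 /min, emax = 330 g (k = 0.2403)
#>  param   estimate      lower      upper level ...
#>  theta 30.1880938 29.1385859 31.2641343  0.95
#>      r  0.1488423  0.1370832  0.1606159  0.95
```

Despite two-second timing jitter and average-bite-size intake, the true
values (30, 0.15) sit inside both intervals. Prediction error against the
true curve:

```r
err <- curve_error(p, fit$estimates, meal$bites)
#> timing RMSE 0.068 min, intake RMSE 1.40 g, timing pseudo-R2 0.9996
```

so recovered parameters mistime bites by about four seconds and misplace
cumulative intake by about a gram and a half, explaining >99.9% of the
variance in true bite timings.

The full validation study — generate 500 reference meals, build feasible
parameter distributions for both models, draw 100 true cases, simulate
all three conditions, fit everything with profile CIs, and run the
recovery battery — is one call:

```r
study <- run_study(study_config(seed = 1))
print(study)
#>   quadratic constant           coverage 1.00/1.00/1.00 | distinct(any) 100% | excl 0
#>   ...
#>   lode      measurement_error  coverage 0.95/0.96 | distinct(any) 100% | excl 0
write_study(study, "study_out")   # CSV/JSON artifact tree + manifest
```

A thin command-line front end (`exec/bitecurve`) exposes the same
pipeline as subcommands (`generate`, `simulate`, `fit`, `recover`,
`run-all`) for shell use.

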