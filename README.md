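# nestrec

Incubation-recess detection and analysis from nest temperature loggers.

Arctic-breeding shorebirds interrupt incubation with *recesses* — off-nest
bouts recorded by a thermologger in the nest cup as sharp temperature
drops. Most recesses are short foraging trips of a few minutes; a small
second class of *extended* recesses lasts for hours and is associated with
cold weather and poor body condition. nestrec implements the full analysis
chain for this problem on tidy tables:

* **Detection** — per local calendar day, a recess is a maximal run of
  minutes strictly below (daily maximum − 4.5 °C), lasting ≥ 3 min; the
  legacy (daily median − 3 °C) rule is kept for comparison. Gaps are never
  interpolated; midnight-crossing runs keep their onset-day threshold.
  Quality filters (≥ 24 h monitoring, 37.5 °C daily-max floor, manual
  exclusions, capture artifacts) annotate rather than silently drop.
* **Classification** — the short/extended boundary is the *antimode* of
  the bimodal log-duration kernel density (two modes required, critical-
  bandwidth escalation, errors on unimodal samples), with a 1000-resample
  nonparametric bootstrap CI, optionally stratified by year and site.
* **Covariates** — mean ground temperature from inactive-nest loggers over
  half-open pre-onset windows of 1/2/6/12/24 h; body condition as the
  scaled mass index `SMI = mass · (L0 / tarsus)^b_SMA` with the SMA
  exponent fitted from ln mass on ln tarsus; day/night period
  (night = 17:00–09:00); incubation date.
* **Inference** — lme4-backed mixed models with a nest random intercept:
  binomial GLMM for extended-recess occurrence, Gaussian LMMs for
  durations and total daily recess duration (TDR); AIC selection of the
  temperature window; Nakagawa marginal/conditional R²; simple slopes and
  closed-form Johnson–Neyman intervals for the temperature × body-condition
  interaction, with an FDR-controlled critical value reported alongside
  the nominal one.
* **Synthetic studies** — `simulate_study()` generates logger-realistic
  nest and ground traces with planted, fully known behavioural truth
  (hazard-driven bouts, logistic occurrence on 12 h temperature,
  interaction-driven extended durations), so every stage is testable
  without field data.

Everything takes a data frame first and returns a tibble; fitted models
have broom-style `tidy()` / `glance()` methods and ggplot2 plot functions
(`plot_trace()`, `plot_duration_distribution()`, `plot_johnson_neyman()`).

## Worked example

```r
library(nestrec)

report <- run_pipeline(run_config(
  seed = 42,
  sim = sim_params(n_nests = 12, days_per_nest = 6),
  n_boot = 100
))
report$threshold
```

```
Recess duration threshold (pooled): antimode 84.0 min (modes 6.9 / 332.5)
  95% bootstrap CI [77.4, 163.2] (100 resamples, 0 failed)
```

The antimode is the objective boundary between short and extended
recesses; the CI is the percentile bootstrap over duration resamples. On
this deliberately small run (~1400 recesses, ~35 of them extended) the
valley between the modes is flat and the boundary imprecise — at study
scale (63 nests, ~7500 recesses; see the acceptance script) it lands
near 140 min with a CI of roughly [110, 155].

```r
report$models$occurrence$window$table
```

```
# A tibble: 5 × 7
  window_hours   aic delta_aic r2_marginal r2_conditional n_obs supported
         <dbl> <dbl>     <dbl>       <dbl>          <dbl> <dbl> <lgl>
1            1  437.     23.0       0.104          0.104   1392 FALSE
2            2  434.     19.8       0.124          0.124   1392 FALSE
3            6  420.      5.27      0.212          0.212   1392 FALSE
4           12  414.      0         0.242          0.242   1392 TRUE
5           24  439.     24.3       0.0930         0.0930  1392 FALSE
```

The AIC window comparison identifies the 12 h pre-onset ground-temperature
average as the best predictor of whether a recess is extended (the
generator's true dependence), with no other window within ΔAIC ≤ 2.
`tidy(report$models$occurrence$fit, raw_units = TRUE)` returns the logit
slope per °C; `report$models$duration_extended$jn` holds the conditional
temperature slopes at the minimum/median/maximum body condition and the
Johnson–Neyman body-condition bounds (unadjusted and FDR-adjusted).

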