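---
title: "Detecting and modelling incubation recesses from nest thermologgers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modelling incubation recesses from nest thermologgers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Arctic-breeding shorebirds such as the sanderling (*Calidris alba*) incubate
in an environment where leaving the nest is costly for the eggs but staying
is costly for the parent. Uniparental incubators interrupt incubation with
*recesses* — off-nest bouts, mostly short foraging trips, occasionally long
"extended" absences of several hours that are thought to be
self-maintenance responses to cold spells. nestrec turns 1-minute nest
temperature traces into recess records and fits the statistical models that
quantify how temperature and body condition shape this behaviour.

This vignette documents the methods, the tunable parameters, the synthetic
study generator used for validation, and the numerical choices made where
the underlying protocol leaves details open.

## Recess detection

A nest logger reads close to incubation temperature (~38 °C) while the bird
sits, and relaxes toward ground temperature when it leaves. For each local
calendar day we compute a detection threshold from the nest trace itself:

* **max-drop rule (default)**: daily maximum − 4.5 °C,
* **median-drop rule (legacy)**: daily median − 3 °C, usable only on days
  whose median stays above 36 °C.

A recess is a maximal run of minutes *strictly below* threshold lasting at
least 3 minutes (shorter dips are within the uncertainty of scoring exact
onset and end times). Choices the protocol leaves open, fixed here:

* The "24-hour period" over which the maximum is taken is the local
  calendar day; a run that crosses midnight keeps its onset-day threshold
  and is reported as a single recess. This keeps detection deterministic
  and consistent with per-day bookkeeping.
* A minute exactly *at* threshold counts as incubation (strict inequality);
  the tie-break must be fixed somewhere and this is the conservative side.
* Gaps in the record (missing minutes) terminate runs and are excluded from
  every statistic. Nothing is interpolated: detection must not hallucinate
  temperatures.
* Total daily recess duration (TDR) splits midnight-crossing recesses
  between days, so daily TDR never exceeds 1440 min and summing TDR over
  days reproduces total detected recess minutes exactly.

The median rule is retained for comparison (`compare_methods()`): both
rules agree on short recesses, but a long absence drags the daily median
below the 36 °C usable-recording floor, so under the legacy protocol the
whole day — extended recess included — is discarded. This is the
quantitative argument for the max-drop rule.

Quality filtering keeps nests monitored ≥ 24 h and days whose maximum nest
temperature reaches 37.5 °C (the 36 °C incubation floor plus a nominal
1.5 °C nest-vs-ground offset, kept as an explicit named constant because
the offset's provenance is a convention, not a law). Whether that floor
should be applied to the nest trace or to the ground reference is
ambiguous in the field literature; we apply it to the nest trace, which is
the record actually being judged, and expose it as configuration. Days
flagged as erratic on inspection and recesses overlapping captures of the
incubating bird are removed with explicit reason codes; every exclusion is
accounted for, so `records_in = records_out + excluded` at each stage.

## Classifying short vs extended recesses

Recess durations are strongly bimodal: a large mode around minutes-long
foraging trips and a small mode of multi-hour absences. The boundary is
estimated, not chosen: a Gaussian kernel density on log-duration (both
modes are roughly symmetric there) gives two local maxima, and the local
minimum between them — the **antimode** — is the classification threshold.
A recess exactly at the threshold is extended (the extended class is
defined as "at least the cutoff").

Bandwidth is the one real tuning decision, and it plays two different
roles that want different amounts of smoothing. Mode *counting* needs a
heavily smoothed density: starting from the Sheather–Jones base bandwidth,
the smoothing is escalated to the smallest multiple with at most two local
maxima (for a Gaussian kernel the mode count is non-increasing in
bandwidth, so this critical bandwidth is well defined), and a sample that
is unimodal already at the base bandwidth is an error ("no antimode")
rather than a silently invented threshold. Locating the *minimum*,
however, is biased by that much smoothing, so the antimode is refined as
the density minimum between the located modes at half the critical
bandwidth (never below the base bandwidth, which keeps the valley between
well-separated modes smooth). The
bootstrap freezes the base bandwidth at its full-sample value across
resamples, so the CI reflects sampling variability of the minimum rather
than bandwidth-rule jitter. A fixed multiplier can be supplied to pin the
bandwidth entirely (single-stage, strict two-mode check).

Uncertainty comes from a nonparametric bootstrap (default 1000 resamples,
percentile 95% CI; the interval type is a choice — percentile is the
assumption-light default). Resamples in which no valid two-mode estimate
exists are counted and excluded; more than half failing aborts the
estimate. Thresholds can be estimated per (year, site) stratum with a
pooled fallback for small strata; the pooled threshold is the default for
labelling because stratum CIs typically overlap.

Strategy assignment (uniparental vs biparental) uses a linear discriminant
on daily recess count and duration whose coefficients come from an
external calibration on nests of known strategy; they are deliberately
injected via configuration rather than re-derived. A single
biparental-to-uniparental changepoint in the daily labels marks a *swap*
nest (desertion of one breeder).

## Covariates

* **Pre-recess ground temperature**: site-level reference built as the
  per-minute mean across loggers in inactive nests, then averaged over the
  half-open window [onset − h, onset) for h ∈ {1, 2, 6, 12, 24} hours.
  The onset minute is excluded. Windows under 50% coverage yield missing
  values (the coverage floor is configurable); covered minutes are
  averaged as-is. How multiple ground loggers combine is not prescribed by
  the field protocol; the mean is implemented with the combiner exposed.
* **Body condition**: scaled mass index, `SMI = mass * (L0 / tarsus)^b`,
  with `b` the standardized-major-axis slope of ln mass on ln tarsus
  (OLS slope divided by Pearson r) and `L0` the mean tarsus of the sample
  by default (configurable to reproduce a published reference length).
  Condition is one number per bird: birds are measured once during
  incubation and population-level mass shows no seasonal trend worth
  modelling here.
* **Day/night**: under permanent Arctic daylight the behavioural "night"
  is 17:00–09:00 local clock time (960 min), "day" 09:00–17:00 (480 min);
  09:00 belongs to day, 17:00 to night.
* **Incubation date**: days since the estimated start of incubation.

## Models

Three families, one fitting surface (`fit_mixed_model()`, backed by lme4
with lmerTest for Satterthwaite degrees of freedom):

1. **Occurrence**: extended (1) vs short (0) recess — binomial GLMM, logit
   link, Laplace approximation.
2. **Duration**: Gaussian LMMs fit separately to extended and short
   recesses (the bimodal marginal rules out one model of all durations).
3. **TDR**: Gaussian LMMs on nest-days, separately for days with and
   without an extended recess.

All include a nest random intercept; numeric predictors are Z-scored
(centers and scales are kept so every slope can be reported per °C, per
gram, per day). Gaussian models are fit by maximum likelihood, not REML,
whenever AICs are compared across fixed-effect structures — AIC is not
comparable otherwise; REML is available for final variance estimates.

The averaging window for pre-recess temperature is selected by AIC over
{1, 2, 6, 12, 24} h on the common complete-case observation set (AICs on
differing observation sets are an error, not a warning). Windows within
ΔAIC ≤ 2 of the best are reported as equally supported.

The temperature × body-condition interaction is retained when it raises
the marginal Nakagawa R² — the variance-partition criterion used in this
literature — compared at two decimals (the precision at which such values
are reported), with ties going to the simpler model; both fits and both
AICs are always reported. Marginal R² is fixed-effect variance over total
(fixed + random + residual) variance on the link scale; conditional R²
adds the random-intercept variance to the numerator; the binomial-logit
residual variance is the theoretical π²/3.

Interactions are probed by simple slopes and Johnson–Neyman intervals: the
conditional temperature slope `s(m) = b_T + b_TM·m` with variance
`Var(b_T) + m²Var(b_TM) + 2m·Cov`, reported at the minimum, median and
maximum observed body condition, and the moderator values where
`s(m)² = t*²·Var[s(m)]` solved in closed form. Because the boundary is a
family of tests over the moderator range, a second, false-discovery-rate
version inflates t\* to the smallest critical value at which the expected
share of false positives among the significant observed moderator values
stays below α; both unadjusted and FDR bounds are always reported.
Degrees of freedom: Satterthwaite per probed slope (via lmerTest contrast
tests), residual df for the JN quadratic (flagged in the output), Wald z
for binomial fits.

The occurrence fit is also summarized as an average per-degree change:
the mean, over the observed integer temperature range, of the relative
change in predicted probability per +1 °C (covariates at their means,
random effects at zero). Because "percent change per degree" is
scale-ambiguous, the constant odds-scale version `exp(β per °C) − 1` is
provided alongside.

## The synthetic study generator

Real deployments cannot carry ground truth, so validation runs on
`simulate_study()`: ground-reference loggers (diurnal sinusoid peaking
mid-afternoon + slowly decorrelating AR(1) weather + logger noise), nests
whose bouts are planted by a per-minute initiation hazard (reduced during
the 17:00–09:00 quiet phase), a logistic extended-vs-short choice driven
by the 12 h pre-onset temperature, and an extended-duration model with a
6 h temperature × body-condition interaction. During a recess the nest
trace relaxes exponentially toward ground temperature (time constant 1 min
by default); rewarming on return is treated as immediate at 1-minute
resolution, which is the aggressive-but-realistic end of contact
incubation and makes planted onset/end minutes exactly recoverable.

Defaults are calibrated once to the qualitative regime reported for this
system and then left alone: ~20–24 recesses per day, duration modes near
7 and 340 min with ~2–3% extended, ground temperatures spanning roughly
0–26 °C across diurnal cycle, weather and a season-staggered nest start,
occurrence slope −0.22 per °C (≈ 20% lower odds per degree), and
extended-duration slopes running from about −21 min/°C for the poorest
birds to ≈ 0 for the best (interaction +0.8 min per °C per gram). The
extended-duration noise is set so the duration model explains ~10–20% of
variance by fixed effects, matching the regime in which these models are
actually fit. What the generator does *not* emulate: weather fronts and
precipitation, predation and hatching events, logger drift, probe
displacement, and erratic traces (the latter can be injected through the
manual-exclusion and capture configuration to exercise the filter paths).
Passing tests therefore validate the machinery and its statistical
behaviour under known truth, not any claim about real nests.

Problem sizes used by the test-suite experiments: detection and recovery
checks run on 20 nests × 10 days (200 nest-days); antimode bootstrap
coverage uses 100 replicates of n = 5000 with 1000 bootstrap resamples
each; occurrence-slope recovery uses 63 nests × 6 days (~8000 bouts), the
window-selection and interaction-stability experiments 20 replicates of
40 × 5 and 35 × 7 nests respectively. These sizes mirror the study regime
the generator emulates.

## Known limitations

* Detection is threshold-based; there is no biophysical egg-cooling model,
  so very shallow absences on hot days (nest–ground gap under ~5 °C) are
  undetectable in principle under the 4.5 °C rule.
* The antimode is undefined for genuinely unimodal duration samples; the
  estimator refuses rather than extrapolates, so sparsely sampled strata
  need the pooled fallback.
* JN bounds are reported even when far outside the observed moderator
  range; users should read them against the observed range (the plot
  function draws both).
* The occurrence model's per-degree probability change depends on the
  covariate profile at which it is evaluated; the default (means, random
  effects at zero) is one defensible choice among several, which is why
  the odds-scale version is reported alongside.

## A worked run

```{r, eval = FALSE}
library(nestrec)

report <- run_pipeline(run_config(
  seed = 42,
  sim = sim_params(n_nests = 12, days_per_nest = 6),
  n_boot = 100
))
report$threshold
tidy(report$models$occurrence$fit, raw_units = TRUE)
report$models$occurrence$window$table
plot_duration_distribution(report$recesses, report$threshold)
```

The same stages run from the shell via the thin wrapper in
`inst/scripts/nestrec` (`simulate`, `run`), and `scripts/acceptance.R`
re-runs the study-scale pipeline end to end and writes its headline
quantities as JSON.
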