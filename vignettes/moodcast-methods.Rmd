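---
title: "Forecasting hourly depressed mood: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting hourly depressed mood: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moodcast)
```

moodcast predicts a person's depressed mood one hour ahead from passively
sensed smartphone data collected in an ecological momentary assessment (EMA)
design: hourly on-the-hour sensor records (location, weather, ambient light,
heart rate and heart-rate variability, outgoing calls) and mood prompts
("sad" and "lonely", each rated 0–100) delivered during self-reported wake
hours. This vignette explains the modelling machinery, the synthetic cohort
generator that stands in for raw study data, and the design decisions taken
where more than one reasonable choice existed.

## The two-phase rolling-window model

For every target hour $t$ the pipeline trains only on the trailing 24-hour
window $[t-24, t)$ and predicts hour $t$ out of sample, so the temporal
direction is never reversed: no model ever sees an outcome from hour $t$ or
later. Training pairs are *concurrent* (features$_s$ → outcome$_s$) for
$s \in [t-24, t)$, applied to features$_t$ to predict outcome$_t$; a
lag-features-only variant was considered and rejected because concurrent
pairing is the only reading compatible with per-hour windows that predict
"the next hour ... from the next hour's passive data".

Within a window, modelling proceeds in two phases:

1. **Nomothetic stage.** A single gradient-boosted tree ensemble
   (xgboost; 50 rounds, depth 3, learning rate 0.3 by default) is fitted to
   the pooled window, targeting the *within-person-centered* outcome — each
   person's training-window mean is subtracted — which makes the stage a
   model of intraindividual variability only. Its predictions are never
   reported; they are *stacked* as one extra feature into phase 2. The
   stacked values attached to training rows are out-of-fold (3 person-blocked
   folds inside the window) so that the downstream model sees an honestly
   out-of-sample feature; hour-$t$ rows receive full-model predictions.
2. **Idiographic stage.** One randomized-forest regression (ranger) per
   person per window per imputation, fitted on all features plus the stacked
   prediction, with observation weights 1.0 for the focal person and 0.2 for
   everyone else. The forest therefore leans strongly on the person's own
   patterns while borrowing strength from the cohort. Hyperparameters are
   chosen by grid search over three per-split candidate counts (`mtry`,
   evenly spaced integers in $[1, p]$) crossed with two split rules
   (variance, extremely randomized trees), with ties broken toward the
   smaller candidate count and then the variance rule (more regularised
   first).

Grid-search evaluation never touches hour $t$: by default candidates are
ranked by the forest's out-of-bag (OOB) error, the standard internal
cross-validation for random forests; a 3-fold person-blocked
cross-validation inside the window is available (`tune_method = "cv"`). OOB
was preferred because it ranks candidates as reliably at these window sizes
(~100–400 rows) while fitting 6 rather than 19 forests per model — a
material difference when a full run fits thousands of models (31 persons ×
144 target hours = 4464 per imputation). Tuning forests use half the trees
of the final fit (`tune_trees`), since OOB rankings stabilise well before
the full ensemble size.

Every fit receives a child seed derived deterministically from the master
seed and the (imputation, hour, person) coordinates, so results are
independent of execution order and parallelism degree, and any single fit is
reproducible in isolation.

### Weighting degeneracies

Two exact identities anchor the weighting implementation: equal weights
reproduce the unweighted pooled forest, and zero other-weight reproduces the
forest fit on the person's rows alone (zero-weight rows are dropped before
fitting, and constant weight vectors are passed as "no weights", which makes
both identities hold bit-for-bit under a shared seed).

## Outcome and panel conventions

* The momentary outcome is the arithmetic mean of whichever of "sad" and
  "lonely" are present (equal weights; the items are treated as parallel
  indicators of depressed affect). The combination rule is a documented
  default — averaging, summing and modelling the items separately are all
  defensible — and is switchable by supplying your own `mood` column.
* Hours are 0-based integers from cohort start; windows are half-open
  $[t-24, t)$; records are stamped on the hour. Call events are summed
  within each clock hour; other sensors are point-read as the latest sample
  at or before the hour mark.
* RMSSD is computed from inter-beat intervals as
  $\sqrt{\mathrm{mean}(\Delta \mathrm{IBI}^2)}$; it is translation-invariant
  and scales linearly, both asserted in the tests.
* Categorical features (`location_source`, `location_type`) are one-hot
  encoded against a dictionary frozen once per run, so the design width $p$
  is identical in every window. Raw latitude/longitude enter as numeric
  features; no derived mobility features are added.

## Multiple imputation

Missing sensor cells are completed $m$ times (default 5; at least 2) by
chained-equation iterative conditional draws: each incomplete variable is
regressed on the other completed fields plus person identity and hour-of-day
harmonics, and missing cells are redrawn from the normal predictive
distribution, clamped to the person's observed range (cohort range when the
person has fewer than 3 observations). Categorical fields are drawn from
person-level (else cohort-level) observed frequencies.

Two deliberate restrictions matter:

* **Sensors never see moods.** Sensor variables are imputed from sensors
  only; the mood items are imputed last. Combined with the next point, this
  guarantees that corrupting future outcomes cannot change any model input —
  the temporal-leakage guard holds bit-for-bit even though imputation is fit
  on the whole panel.
* **Models train only on genuinely observed outcomes.** Imputed *sensor*
  values are used as features everywhere, but rows whose mood was never
  answered are excluded from training and evaluation. Imputed moods are kept
  for the lagged-outcome sensitivity analysis and for plotting.

Observed cells are never altered, and a panel with nothing missing yields
$m$ identical copies.

## Evaluation

Predictions are pooled across imputations by averaging per (person, hour),
then summarised as (a) the pooled Pearson correlation between observed and
predicted mood with a Fisher-z interval ($z \pm 1.96/\sqrt{n-3}$,
back-transformed), and (b) per-person correlations averaged on the Fisher-z
scale (atanh → mean → tanh), with a $t$ interval on the z scale
(df = persons − 1). Pooling pairs across imputations before correlating —
rather than applying Rubin's rules to per-imputation correlations — follows
the way the source analyses averaged multiply imputed points, and is the
main deviation candidate a re-analysis might revisit. Persons with fewer
than 3 pairs or degenerate variance are flagged and excluded from the
average rather than silently dropped. Correlations of exactly ±1 are clamped
to $1 - 10^{-7}$ before atanh, with a classed warning.

## Sensitivity analyses

Both are linear mixed models with a person random intercept, fitted by REML
with Satterthwaite degrees of freedom (the fractional df reported by such
analyses imply a Satterthwaite-type approximation):

* **Race moderation**: `outcome ~ prediction * race + (1 | person)`, with a
  joint F test on all prediction-by-race interaction terms. The reference
  race level is the most frequent category. The test is refused (not
  errored) when fewer than two race levels have at least two persons.
* **Lagged-outcome control**: `outcome ~ prediction + lag(outcome) +
  (1 | person)`, reporting the prediction slope — the check that the models
  are not merely carrying the last mood forward. The lag is strictly hour
  $t-1$; when that hour's outcome was unobserved the imputation-averaged
  value is used, and rows with no defined lag are dropped. Near-collinearity
  between prediction and lag (|r| > 0.999) raises a classed warning.

Setting `random_intercept = FALSE` in either function drops to ordinary
least squares, the boundary case with zero random-intercept variance, which
the tests compare against `stats::lm` oracles.

## The synthetic cohort generator

No raw data from hourly mood-sensing studies of this design are publicly
deposited, so the generator is a first-class module: it emulates the study
conditions and retains its own ground truth so that every downstream stage
is testable. Defaults encode the emulated design: 31 persons, 8 days of
hourly sensing, prompts during 16 wake hours on the first 7 days at 46%
compliance (≈52 completed prompts per person), and a severity mix in which
most of the cohort scores severe to extremely severe on the 14-item DASS
depression subscale (items 0–3, score range exactly 0–42).

The latent mood model is
$\text{latent}_{it} = \alpha_i + A \sin(2\pi (h - \phi)/24) + e_{it}$, with
$e$ a stationary AR(1) chain (persistence 0.6, innovation SD 8 mood units by
default) and a 24-h sinusoid (amplitude 6, worst in the early morning). The
paper-gap here is real — no generating model is stated anywhere — and AR(1)
plus a diurnal cycle plus a person intercept is the minimal process
consistent with hour-to-hour mood fluctuation findings. "Sad" and "lonely"
are independent noisy readouts of the latent state clamped to [0, 100]; the
readout SD default (9.9) was calibrated once so their pooled correlation is
≈0.66, matching the convergent validity reported for the two items. An
optional zero-inflation knob emulates floor effects without asserting a
particular response distribution.

Sensors are generated around realistic bases with cohort-level coupling
directions (worse mood → higher heart rate, lower RMSSD, fewer outgoing
calls, less ambient light, less movement), person-specific deviations
(SD `coupling_heterogeneity`), an overall `coupling_scale`, and clamps to
physically plausible ranges. Weather is cohort-shared (one study site).
Locations are a small set of anchor points (home, university, gym,
restaurant, outdoors) with Gaussian jitter; each person's *home* anchor is
their own address, and resting heart-rate/RMSSD baselines differ across
persons — stable interindividual sensor differences of the kind real
sensing data shows, and the features through which pooled tree models can
(partly) personalise. All of these magnitudes are configurable
(`home_scatter_sd`, `hr_baseline_sd`, `rmssd_baseline_sd`).

### What passing tests do and do not show

The generator produces Gaussian-ish, stationary, MCAR-missing data with
couplings that are constant within person over the week. Real sensing data
has heavier tails, regime shifts (weekends, illness), informative
missingness (people avoid their phone when distressed), and time-varying
couplings. Passing the recovery tests therefore shows the *pipeline* is
correct and can extract signal that is present; it does not show that real
mood is predictable at any particular accuracy.

### Test regimes and problem sizes

Several recovery and calibration properties are checked on purpose-built
generator regimes:

* **Signal recovery** (pooled out-of-sample $r \ge 0.8$): 15 persons ×
  8 days, `coupling_scale = 2`, low noise (`noise_sd = 1.5`,
  `item_noise_sd = 1`), a pronounced diurnal cycle (amplitude 10) and small
  level differences. Strong shared diurnal structure is the regime in which
  tree ensembles transmit sensor signal most faithfully; with purely
  idiosyncratic AR dynamics the forests plateau near $r \approx 0.7$ at
  these window sizes because the signal is spread across many weak linear
  features.
* **Null calibration** (pooled-r CI covers 0 in ≥90% of 20 seeds):
  `coupling_scale = 0` *and* no stable person differences
  (`person_intercept_sd = 0`, zero DASS slope) *and* no diurnal cycle.
  The extra zeros are necessary, not convenient: with person levels or a
  diurnal cycle present, a correct pipeline legitimately predicts them (from
  person fingerprints and weather-borne time-of-day information) and pooled
  $r > 0$ under zero coupling — that would be signal, not miscalibration.
* **Idiographic benefit** (person-weighted beats pooled when ⅓ of persons
  have sign-flipped couplings): a cohort whose *only* interindividual
  difference is the coupling direction (no level differences, no sensor
  fingerprints), so the pooled stage cannot personalise through features and
  the weighting has to do the work.
* **Monotonicity** (pooled r non-decreasing in coupling scale over
  {0, 0.5, 1, 2}): the same homogeneous regime, so the baseline at scale 0
  sits near zero.

Cohort sizes and target-hour subsets in the tests and the acceptance script
(for example, every 3rd or 6th target hour) are the package's own
single-CPU-friendly choices; per-(person, hour) predictions are independent
of which other hours are evaluated, so subsetting hours changes only the
number of evaluation pairs, not their values.

## Numerical choices and degenerate inputs

* Seeds are 32-bit; `derive_seed()` mixes coordinates with multiplicative
  hashing modulo $2^{31}-1$.
* The AR(1) chain is initialised from its stationary distribution, so the
  first simulated hour is not a transient.
* Empty training windows are skip signals recorded in the fit ledger, not
  errors; a window with a constant outcome fits and predicts that constant.
* Correlation of fewer than 3 pairs or zero variance is an "undefined"
  signal (classed warning + `NA`), never a propagated `NaN`.
* The Fisher CI at exactly $n = 3$ is reported as $[-1, 1]$ (the z interval
  has infinite width there).
* Imputation draws are clamped to observed ranges, so a variable can never
  be imputed outside physically observed values; call counts are rounded and
  floored at zero.

## Known limitations

* The idiographic stage models *raw* mood with person weighting; with very
  strong between-person level differences and weak fingerprints its pooled
  correlation is bounded by how well leaf averages can separate person
  levels from ~24 h of data.
* The chained-equation imputer uses linear conditional models; strongly
  nonlinear sensor dependencies are imputed at reduced fidelity.
* One nomothetic model is fitted per target hour (per imputation); a single
  global nomothetic model reused across hours would be cheaper but would
  blur the rolling-origin design.
* Wake schedules are constant within person across days; real bed/wake
  times drift.
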