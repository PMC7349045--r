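#' Configure a synthetic EMA cohort
#'
#' Builds the configuration object consumed by [generate_cohort()] and its
#' component generators. Defaults emulate an 8-day ecological momentary
#' assessment (EMA) study of 31 undergraduates reporting clinical levels of
#' depression: hourly on-the-hour passive sensing, mood prompts only during
#' self-reported wake hours for the first seven days, and roughly 52 completed
#' prompts per person (16 wake hours x 7 days x 0.46 compliance).
#'
#' The latent depressed-mood process for each person is
#' `intercept_i + diurnal + AR(1)`, where the AR(1) chain has persistence
#' `ar_coefficient` and innovation SD `noise_sd` (mood units on the 0-100
#' scale), and the diurnal term is a 24-h sinusoid of amplitude
#' `diurnal_amplitude`. The observed "sad" and "lonely" items are two
#' independent noisy readouts of the latent state with readout SD
#' `item_noise_sd`; the default (9.9) is calibrated so their pooled
#' correlation is about 0.66, the convergent validity reported for the two
#' PANAS-X items.
#'
#' @param n_persons Number of persons in the cohort.
#' @param n_days Days of enrollment (the hourly grid spans `n_days * 24` hours).
#' @param wake_hours_per_day Hours per day a person is awake (mood prompts are
#'   only delivered during wake hours).
#' @param prompt_days Number of days (from day 1) on which mood prompts are
#'   delivered; default `min(n_days, 7)`.
#' @param compliance_rate Probability that a scheduled wake-hour prompt is
#'   answered.
#' @param ar_coefficient AR(1) persistence of latent mood, in (-1, 1).
#' @param diurnal_amplitude Amplitude (mood units) of the 24-h sinusoidal mood
#'   cycle.
#' @param noise_sd Innovation SD (mood units) of the latent AR(1) chain.
#' @param item_noise_sd Readout SD (mood units) of each mood item around the
#'   latent state.
#' @param intercept_mean,person_intercept_sd Mean and between-person SD of the
#'   latent mood intercept.
#' @param intercept_dass_slope Mood-units shift in the intercept per point of
#'   baseline DASS depression above the sample centre.
#' @param coupling_scale Overall effect size of latent mood on the sensors
#'   (0 = sensors carry no mood signal).
#' @param coupling_heterogeneity SD of person-specific deviations around the
#'   cohort-level coupling coefficients.
#' @param sign_flip_fraction Fraction of persons (taken from the start of the
#'   roster) whose whole coupling vector is sign-flipped, for testing whether
#'   person-weighted models beat pooled ones.
#' @param home_scatter_sd SD (degrees) of person home-anchor offsets — how
#'   spread out the cohort's homes are.
#' @param hr_baseline_sd,rmssd_baseline_sd Between-person SDs of resting heart
#'   rate (bpm) and RMSSD (ms) baselines.
#' @param sensor_missing_rate Independent missingness probability applied to
#'   each sensor cell (call counts excluded: an absent call log reads 0).
#' @param zero_inflation Probability that an answered prompt reports 0 on both
#'   items regardless of latent state (floor effect on the 0-100 scale).
#' @param race_distribution Named probability vector over race groups; must sum
#'   to 1. Default mirrors a 31-person cohort (21/31 Caucasian, 5/31 Asian
#'   American, 2/31 African American, 2/31 Other, 1/31 Hispanic/Latino).
#' @param seed Integer master seed; every draw in the generator derives from it.
#'
#' @return A list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_persons = 4, n_days = 2, seed = 1)
#' @export
cohort_config <- function(n_persons = 31,
                          n_days = 8,
                          wake_hours_per_day = 16,
                          prompt_days = NULL,
                          compliance_rate = 0.46,
                          ar_coefficient = 0.6,
                          diurnal_amplitude = 6,
                          noise_sd = 8,
                          item_noise_sd = 9.9,
                          intercept_mean = 35,
                          person_intercept_sd = 10,
                          intercept_dass_slope = 0.4,
                          coupling_scale = 1,
                          coupling_heterogeneity = 0.3,
                          sign_flip_fraction = 0,
                          home_scatter_sd = 0.02,
                          hr_baseline_sd = 5,
                          rmssd_baseline_sd = 8,
                          sensor_missing_rate = 0.05,
                          zero_inflation = 0,
                          race_distribution = c(
                            caucasian = 21, asian_american = 5,
                            african_american = 2, other = 2,
                            hispanic_latino = 1
                          ) / 31,
                          seed = 1L) {
  if (is.null(prompt_days)) prompt_days <- min(n_days, 7)
  cfg <- list(
    n_persons = as.integer(n_persons), n_days = as.integer(n_days),
    wake_hours_per_day = as.integer(wake_hours_per_day),
    prompt_days = as.integer(prompt_days),
    compliance_rate = compliance_rate, ar_coefficient = ar_coefficient,
    diurnal_amplitude = diurnal_amplitude, noise_sd = noise_sd,
    item_noise_sd = item_noise_sd, intercept_mean = intercept_mean,
    person_intercept_sd = person_intercept_sd,
    intercept_dass_slope = intercept_dass_slope,
    coupling_scale = coupling_scale,
    coupling_heterogeneity = coupling_heterogeneity,
    sign_flip_fraction = sign_flip_fraction,
    home_scatter_sd = home_scatter_sd,
    hr_baseline_sd = hr_baseline_sd,
    rmssd_baseline_sd = rmssd_baseline_sd,
    sensor_missing_rate = sensor_missing_rate,
    zero_inflation = zero_inflation,
    race_distribution = race_distribution,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_persons < 1L) {
    rlang::abort("`n_persons` must be >= 1.", class = "moodcast_config_error")
  }
  if (cfg$n_days < 1L) {
    rlang::abort("`n_days` must be >= 1.", class = "moodcast_config_error")
  }
  if (cfg$compliance_rate < 0 || cfg$compliance_rate > 1) {
    rlang::abort("`compliance_rate` must lie in [0, 1].",
      class = "moodcast_config_error"
    )
  }
  if (abs(cfg$ar_coefficient) >= 1) {
    rlang::abort("`ar_coefficient` must satisfy |ar| < 1.",
      class = "moodcast_config_error"
    )
  }
  if (cfg$wake_hours_per_day < 1L || cfg$wake_hours_per_day > 24L) {
    rlang::abort("`wake_hours_per_day` must lie in [1, 24].",
      class = "moodcast_config_error"
    )
  }
  if (cfg$prompt_days < 0L || cfg$prompt_days > cfg$n_days) {
    rlang::abort("`prompt_days` must lie in [0, n_days].",
      class = "moodcast_config_error"
    )
  }
  rd <- cfg$race_distribution
  if (is.null(names(rd)) || any(names(rd) == "") || any(rd < 0) ||
    abs(sum(rd) - 1) > 1e-9) {
    rlang::abort(
      "`race_distribution` must be a named non-negative vector summing to 1.",
      class = "moodcast_config_error"
    )
  }
  if (cfg$sign_flip_fraction < 0 || cfg$sign_flip_fraction > 1) {
    rlang::abort("`sign_flip_fraction` must lie in [0, 1].",
      class = "moodcast_config_error"
    )
  }
  invisible(cfg)
}

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with integer coordinates (such as imputation copy,
#' target hour, person index) into a new seed below 2^31, so that any single
#' model fit or draw in the pipeline is reproducible in isolation and
#' independent of execution order.
#'
#' @param master Integer master seed.
#' @param ... Integer coordinates identifying the consumer of the seed.
#' @return A single integer seed.
#' @export
derive_seed <- function(master, ...) {
  ids <- c(...)
  h <- as.double(abs(as.integer(master)) %% 2147483647)
  for (i in ids) {
    h <- (h * 48271 + (as.double(i) + 1) * 1299721 + 7) %% 2147483647
  }
  as.integer(h)
}

# sensors that latent mood is coupled to, with cohort-level directions:
# worse mood -> higher heart rate, lower HRV, fewer calls, less light,
# less movement. Magnitudes are in SD units of each sensor's noise.
coupling_base <- function() {
  c(hr_mean = 0.5, hrv_rmssd = -0.5, outgoing_calls = -0.5,
    light_level = -0.4, location_speed = -0.3)
}
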