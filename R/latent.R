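#' Simulate a person's latent depressed-mood trajectory
#'
#' Latent mood is the person's intercept plus a 24-h sinusoid (peak in the
#' early morning, when depressed mood tends to be worst) plus a stationary
#' AR(1) chain with persistence `ar_coefficient` and innovation SD `noise_sd`.
#' The chain is initialised from its stationary distribution, so the first
#' hour is not special. With all stochastic and cyclic terms at zero the
#' trajectory is constant at the intercept.
#'
#' @param profile One row of the tibble returned by [generate_profiles()].
#' @param config A [cohort_config()].
#' @return A tibble with `person_id`, `hour_index` (0-based) and `latent`
#'   (mood units), one row per hour over `n_days * 24` hours.
#' @export
simulate_latent_mood <- function(profile, config) {
  validate_cohort_config(config)
  phi <- config$ar_coefficient
  n_hours <- config$n_days * 24L
  pidx <- as.integer(sub("^p", "", profile$person_id))
  set.seed(derive_seed(config$seed, 202L, pidx))
  e <- numeric(n_hours)
  stat_sd <- config$noise_sd / sqrt(1 - phi^2)
  prev <- stats::rnorm(1, 0, stat_sd)
  innov <- stats::rnorm(n_hours, 0, config$noise_sd)
  for (t in seq_len(n_hours)) {
    prev <- phi * prev + innov[t]
    e[t] <- prev
  }
  hour <- seq_len(n_hours) - 1L
  diurnal <- config$diurnal_amplitude * sin(2 * pi * (hour %% 24 - 4) / 24 + pi / 2)
  tibble::tibble(
    person_id = profile$person_id,
    hour_index = hour,
    latent = profile$mood_intercept + diurnal + e
  )
}

# within-person SD of the latent process (AR(1) stationary + sinusoid),
# used to standardise latent mood before applying sensor couplings
latent_within_sd <- function(config) {
  sqrt(config$noise_sd^2 / (1 - config$ar_coefficient^2) +
    config$diurnal_amplitude^2 / 2)
}
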