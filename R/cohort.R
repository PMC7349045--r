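#' Apply prompt-compliance and sensor missingness to a complete panel
#'
#' Mood observations are removed outside wake hours and outside the prompting
#' days, and retained within them with probability `compliance_rate`, so the
#' expected number of completed prompts per person is
#' `wake_hours_per_day * prompt_days * compliance_rate`. Every sensor cell
#' except the call count is independently masked with probability
#' `sensor_missing_rate` (an absent call log reads 0, so calls stay observed).
#'
#' @param panel A complete hourly panel (tibble) as built by [generate_cohort()].
#' @param config A [cohort_config()].
#' @param profiles The profile tibble (for wake schedules).
#' @return The panel with `NA`s injected.
#' @export
apply_missingness <- function(panel, config, profiles) {
  validate_cohort_config(config)
  set.seed(derive_seed(config$seed, 505L))
  panel <- dplyr::left_join(
    panel,
    dplyr::select(profiles, "person_id", "wake_hour"),
    by = "person_id"
  )
  promptable <- panel$awake & (panel$hour_index %/% 24L) < config$prompt_days
  answered <- promptable & stats::runif(nrow(panel)) < config$compliance_rate
  panel$sad[!answered] <- NA_real_
  panel$lonely[!answered] <- NA_real_
  sensor_cols <- setdiff(sensor_feature_names(), "outgoing_calls")
  for (col in sensor_cols) {
    mask <- stats::runif(nrow(panel)) < config$sensor_missing_rate
    panel[[col]][mask] <- NA
  }
  dplyr::select(panel, -"wake_hour")
}

#' Generate a full synthetic cohort panel with retained ground truth
#'
#' Composes [generate_profiles()], [simulate_latent_mood()],
#' [simulate_sensors()] and [apply_missingness()]: the observable panel is the
#' persons-by-hours grid of sensor features plus (possibly missing) momentary
#' "sad" and "lonely" ratings, and the ground truth (latent trajectories and
#' coupling vectors) is kept alongside for recovery tests. Both items are
#' independent noisy readouts of the latent state, clamped to the 0-100
#' response scale; with probability `zero_inflation` an answered prompt
#' reports 0 on both items.
#'
#' @param config A [cohort_config()].
#' @return An object of class `mood_cohort`: a list with `panel` (tibble, one
#'   row per person-hour), `profiles`, `truth` (per person-hour latent mood)
#'   and `config`. Identical configs (including seed) yield identical cohorts.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_persons = 3, n_days = 2, seed = 7))
#' dim(cohort$panel)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  profiles <- generate_profiles(config)
  parts <- purrr::map(seq_len(nrow(profiles)), function(i) {
    prof <- profiles[i, ]
    latent <- simulate_latent_mood(prof, config)
    sensors <- simulate_sensors(latent, prof, config)
    pidx <- as.integer(sub("^p", "", prof$person_id))
    set.seed(derive_seed(config$seed, 606L, pidx))
    n <- nrow(latent)
    sad <- pmin(100, pmax(0, latent$latent + stats::rnorm(n, 0, config$item_noise_sd)))
    lonely <- pmin(100, pmax(0, latent$latent + stats::rnorm(n, 0, config$item_noise_sd)))
    if (config$zero_inflation > 0) {
      zi <- stats::runif(n) < config$zero_inflation
      sad[zi] <- 0
      lonely[zi] <- 0
    }
    list(
      panel = dplyr::mutate(sensors, sad = sad, lonely = lonely),
      latent = latent
    )
  })
  panel <- purrr::list_rbind(purrr::map(parts, "panel"))
  truth <- purrr::list_rbind(purrr::map(parts, "latent"))
  panel <- apply_missingness(panel, config, profiles)
  structure(
    list(panel = panel, profiles = profiles, truth = truth, config = config),
    class = "mood_cohort"
  )
}

#' @export
print.mood_cohort <- function(x, ...) {
  cat(sprintf(
    "<mood_cohort> %d persons x %d hours (%d person-hours), %d completed prompts\n",
    nrow(x$profiles), x$config$n_days * 24L, nrow(x$panel),
    sum(!is.na(x$panel$sad) | !is.na(x$panel$lonely))
  ))
  invisible(x)
}
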