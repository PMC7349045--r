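# shared fixtures built in code

# small cohort reused by several tests (5 persons x 3 days)
small_cohort <- function(seed = 5, ...) {
  generate_cohort(cohort_config(n_persons = 5, n_days = 3, seed = seed, ...))
}

# fast model configs for pipeline tests
fast_idio <- function(...) {
  idiographic_config(forest_size = 60L, tune_trees = 30L, ...)
}
fast_nomo <- function() nomothetic_config(rounds = 25L)

# a complete tiny panel with a known linear sensor-mood relationship,
# handy for windows/fits without the full generator
toy_panel <- function(n_persons = 3, n_hours = 48, seed = 1,
                      slope = 2, noise = 0) {
  set.seed(seed)
  grid <- tidyr::expand_grid(
    person_id = sprintf("p%02d", seq_len(n_persons)),
    hour_index = 0:(n_hours - 1)
  )
  n <- nrow(grid)
  hr <- rnorm(n, 70, 5)
  mood <- pmin(100, pmax(0, 30 + slope * (hr - 70) + rnorm(n, 0, noise)))
  tibble::tibble(
    grid,
    awake = TRUE,
    latitude = 40.79, longitude = -77.86,
    location_accuracy = 10, location_speed = runif(n),
    location_source = sample(c("gps", "wifi"), n, TRUE),
    location_type = sample(c("home", "university"), n, TRUE),
    temperature = rnorm(n, 15), humidity = runif(n, 30, 90),
    precipitation = 0, light_level = runif(n, 0, 500),
    hr_mean = hr, hrv_rmssd = rnorm(n, 45, 8),
    outgoing_calls = rpois(n, 0.5),
    sad = mood, lonely = mood
  )
}

# null-regime config: no sensor-mood coupling, no stable person differences,
# no diurnal cycle -- mood is unpredictable noise by construction
null_config <- function(seed, n_persons = 6, n_days = 4) {
  cohort_config(
    n_persons = n_persons, n_days = n_days, coupling_scale = 0,
    person_intercept_sd = 0, intercept_dass_slope = 0, diurnal_amplitude = 0,
    seed = seed
  )
}

# high-signal config: strong couplings, a pronounced diurnal cycle, low noise
signal_config <- function(seed, n_persons = 15, n_days = 8, coupling_scale = 2) {
  cohort_config(
    n_persons = n_persons, n_days = n_days, coupling_scale = coupling_scale,
    diurnal_amplitude = 10, noise_sd = 1.5, item_noise_sd = 1,
    person_intercept_sd = 3, intercept_dass_slope = 0.2, compliance_rate = 0.6,
    coupling_heterogeneity = 0.1, sensor_missing_rate = 0.02, seed = seed
  )
}

# sign-flip cohort: the ONLY interindividual difference is the coupling
# direction (no level differences, no sensor fingerprints), so pooled models
# misread the flipped third while person-weighted models can adapt
flip_config <- function(seed, n_persons = 9, n_days = 5) {
  cohort_config(
    n_persons = n_persons, n_days = n_days, coupling_scale = 2, noise_sd = 3,
    item_noise_sd = 2, compliance_rate = 0.8, person_intercept_sd = 0,
    intercept_dass_slope = 0, home_scatter_sd = 0, hr_baseline_sd = 0,
    rmssd_baseline_sd = 0, coupling_heterogeneity = 0.1,
    sensor_missing_rate = 0.02, sign_flip_fraction = 1 / 3,
    prompt_days = n_days, seed = seed
  )
}

# coupling sweep cohort: no level or diurnal structure, so pooled r tracks
# the coupling strength alone
mono_config <- function(seed, coupling_scale) {
  cohort_config(
    n_persons = 6, n_days = 4, coupling_scale = coupling_scale,
    diurnal_amplitude = 0, person_intercept_sd = 0, intercept_dass_slope = 0,
    noise_sd = 3, item_noise_sd = 2, compliance_rate = 0.7,
    coupling_heterogeneity = 0.1, sensor_missing_rate = 0.02,
    prompt_days = 4, seed = seed
  )
}

# run generate -> impute -> pipeline -> pooled r for acceptance-style checks
pipeline_pooled_r <- function(config, hours, pipeline_seed = 1,
                              m = 2, forest_size = 100L) {
  cohort <- generate_cohort(config)
  imputed <- impute_panel(cohort$panel, m = m, seed = derive_seed(config$seed, 7L))
  preds <- run_pipeline(
    imputed,
    hours = hours, seed = pipeline_seed,
    nomothetic = fast_nomo(),
    idiographic = idiographic_config(forest_size = forest_size, tune_trees = 25L),
    fit_persons = "observed"
  )
  list(
    evaluation = evaluate_predictions(preds),
    predictions = preds, cohort = cohort, imputed = imputed
  )
}
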