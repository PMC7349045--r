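test_that("profile generation honours count, score range and determinism", {
  cfg <- cohort_config(n_persons = 31, seed = 1)
  prof <- generate_profiles(cfg)
  expect_equal(nrow(prof), 31)
  expect_true(all(prof$baseline_dass_d >= 0 & prof$baseline_dass_d <= 42))
  expect_identical(prof, generate_profiles(cohort_config(n_persons = 31, seed = 1)))
  # different seed changes the draw
  expect_false(identical(prof, generate_profiles(cohort_config(n_persons = 31, seed = 2))))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_persons = 0), class = "moodcast_config_error")
  expect_error(cohort_config(ar_coefficient = 1), class = "moodcast_config_error")
  expect_error(cohort_config(compliance_rate = 1.2), class = "moodcast_config_error")
  expect_error(
    cohort_config(race_distribution = c(a = 0.5, b = 0.6)),
    class = "moodcast_config_error"
  )
})

test_that("latent mood process has the configured dynamics", {
  # degenerate process: constant at the person intercept
  cfg0 <- cohort_config(
    n_persons = 1, n_days = 2, ar_coefficient = 0, diurnal_amplitude = 0,
    noise_sd = 0, seed = 3
  )
  prof <- generate_profiles(cfg0)
  lat <- simulate_latent_mood(prof[1, ], cfg0)
  expect_equal(nrow(lat), 48)
  expect_equal(lat$latent, rep(prof$mood_intercept[1], 48))

  # pure sinusoid: 24-h period, amplitude exactly as configured
  cfg_sin <- cohort_config(
    n_persons = 1, n_days = 10, ar_coefficient = 0, diurnal_amplitude = 5,
    noise_sd = 0, seed = 3
  )
  lat_sin <- simulate_latent_mood(generate_profiles(cfg_sin)[1, ], cfg_sin)
  dev <- lat_sin$latent - generate_profiles(cfg_sin)$mood_intercept[1]
  expect_equal(max(dev), 5, tolerance = 1e-8)
  expect_equal(min(dev), -5, tolerance = 1e-8)
  expect_equal(dev[1:24], dev[25:48], tolerance = 1e-10)

  # AR(1) persistence recovered from the empirical ACF over many hours
  cfg_ar <- cohort_config(
    n_persons = 1, n_days = 250, ar_coefficient = 0.9, noise_sd = 1,
    diurnal_amplitude = 0, seed = 4
  )
  lat_ar <- simulate_latent_mood(generate_profiles(cfg_ar)[1, ], cfg_ar)
  expect_gt(nrow(lat_ar), 5000)
  acf1 <- stats::acf(lat_ar$latent, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(acf1, 0.9, tolerance = 0.03)
})

test_that("sensor streams respect coupling, sharing and plausibility contracts", {
  # null coupling: sensors statistically independent of latent mood
  cfg0 <- cohort_config(
    n_persons = 1, n_days = 250, coupling_scale = 0, seed = 6
  )
  prof <- generate_profiles(cfg0)
  lat <- simulate_latent_mood(prof[1, ], cfg0)
  sens <- simulate_sensors(lat, prof[1, ], cfg0)
  ct <- stats::cor.test(lat$latent, sens$hr_mean)
  expect_true(ct$conf.int[1] < 0 && ct$conf.int[2] > 0)

  # negative calls coupling recovered by rank correlation
  cfg_c <- cohort_config(
    n_persons = 1, n_days = 250, coupling_scale = 1,
    coupling_heterogeneity = 0, seed = 7
  )
  prof_c <- generate_profiles(cfg_c)
  prof_c$coupling_outgoing_calls <- -0.5
  lat_c <- simulate_latent_mood(prof_c[1, ], cfg_c)
  sens_c <- simulate_sensors(lat_c, prof_c[1, ], cfg_c)
  awake_rows <- sens_c$awake
  rho <- stats::cor(lat_c$latent[awake_rows], sens_c$outgoing_calls[awake_rows],
    method = "spearman"
  )
  expect_lt(rho, -0.1)

  # shared weather: two persons, same hour, identical values
  cfg2 <- cohort_config(n_persons = 2, n_days = 2, seed = 8)
  prof2 <- generate_profiles(cfg2)
  s1 <- simulate_sensors(simulate_latent_mood(prof2[1, ], cfg2), prof2[1, ], cfg2)
  s2 <- simulate_sensors(simulate_latent_mood(prof2[2, ], cfg2), prof2[2, ], cfg2)
  expect_equal(s1$temperature, s2$temperature)
  expect_equal(s1$humidity, s2$humidity)
  expect_equal(s1$precipitation, s2$precipitation)

  # plausibility clamps
  expect_true(all(s1$outgoing_calls >= 0 & s1$outgoing_calls == round(s1$outgoing_calls)))
  expect_true(all(s1$location_source %in% c("gps", "wifi")))
  expect_true(all(s1$humidity >= 0 & s1$humidity <= 100))
  expect_true(all(s1$hr_mean > 0))
})

test_that("missingness matches the prompting design", {
  # full compliance, 24 wake hours, prompts every day: no mood missingness
  cfg_full <- cohort_config(
    n_persons = 3, n_days = 2, wake_hours_per_day = 24, compliance_rate = 1,
    prompt_days = 2, sensor_missing_rate = 0, seed = 9
  )
  co_full <- generate_cohort(cfg_full)
  expect_false(anyNA(co_full$panel$sad))

  # zero compliance: no mood observations at all
  cfg_zero <- cohort_config(n_persons = 3, n_days = 2, compliance_rate = 0, seed = 9)
  expect_true(all(is.na(generate_cohort(cfg_zero)$panel$sad)))

  # study design arithmetic: 16 wake hours x 7 prompting days x 0.46
  # compliance gives close to 52 completed prompts per person
  cfg <- cohort_config(seed = 10)
  co <- generate_cohort(cfg)
  prompts <- co$panel |>
    dplyr::filter(!is.na(sad)) |>
    dplyr::count(person_id)
  expected <- 16 * 7 * 0.46
  se <- sqrt(16 * 7 * 0.46 * 0.54 / 31)
  expect_equal(mean(prompts$n), expected, tolerance = 4 * se / expected)
})

test_that("cohort generation is deterministic and spans the full grid", {
  cfg <- cohort_config(n_persons = 31, n_days = 8, seed = 11)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$panel), 31 * 192)
  expect_identical(co$panel, generate_cohort(cfg)$panel)
  expect_identical(co$truth, generate_cohort(cfg)$truth)
  # ground truth is retained for every person-hour
  expect_equal(nrow(co$truth), 31 * 192)
  # sad/lonely readouts of the same latent state correlate strongly
  pp <- dplyr::filter(co$panel, !is.na(sad))
  expect_equal(cor(pp$sad, pp$lonely), 0.66, tolerance = 0.08)
})

test_that("DASS score generator attains exactly the 0-42 range", {
  expect_identical(dass_score_range(), c(0L, 42L))
  expect_identical(dass_depression_score(rep(0L, 14)), 0L)
  expect_identical(dass_depression_score(rep(3L, 14)), 42L)
  expect_error(dass_depression_score(rep(4L, 14)), class = "moodcast_config_error")
  expect_error(dass_depression_score(rep(1L, 13)), class = "moodcast_config_error")
})
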