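#' Simulate the shared weather stream for a cohort
#'
#' Weather is cohort-shared (a single study site): temperature and humidity
#' follow diurnal sinusoids plus slow AR(1) drift, and precipitation is zero
#' most hours with exponential rainfall amounts otherwise. The stream depends
#' only on the cohort seed, so any two persons see identical weather for the
#' same hour.
#'
#' @param config A [cohort_config()].
#' @param n_hours Number of hourly values (default `n_days * 24`).
#' @return A tibble with `hour_index`, `temperature` (deg C), `humidity`
#'   (percent, clamped to \[0, 100\]) and `precipitation` (mm).
#' @export
simulate_weather <- function(config, n_hours = config$n_days * 24L) {
  set.seed(derive_seed(config$seed, 303L))
  hour <- seq_len(n_hours) - 1L
  ar1 <- function(n, phi, sd) {
    e <- numeric(n)
    prev <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
    innov <- stats::rnorm(n, 0, sd)
    for (t in seq_len(n)) {
      prev <- phi * prev + innov[t]
      e[t] <- prev
    }
    e
  }
  temp <- 16 + 5 * sin(2 * pi * (hour %% 24 - 15) / 24 + pi / 2) + ar1(n_hours, 0.95, 0.4)
  hum <- pmin(100, pmax(0, 60 - 12 * sin(2 * pi * (hour %% 24 - 15) / 24 + pi / 2) +
    ar1(n_hours, 0.9, 2)))
  rain <- ifelse(stats::runif(n_hours) < 0.08, stats::rexp(n_hours, 1 / 1.5), 0)
  tibble::tibble(
    hour_index = hour, temperature = temp, humidity = hum,
    precipitation = round(rain, 2)
  )
}

# anchor points a person moves between; location_type is the anchor category
location_anchors <- function() {
  tibble::tibble(
    location_type = c("home", "university", "gym", "restaurant", "outdoors"),
    lat = 40.7934 + c(0.010, 0.000, 0.006, -0.004, 0.015),
    lon = -77.8600 + c(-0.012, 0.000, 0.008, 0.005, -0.020)
  )
}

#' Simulate a person's hourly sensor stream
#'
#' Produces one row per hour with the full passive-sensing feature set:
#' location (anchor points with Gaussian jitter, GPS/WiFi source, accuracy,
#' speed), cohort-shared weather, ambient light, heart rate, RMSSD heart-rate
#' variability, and summed outgoing calls. Latent mood is standardised within
#' person and pushed into the coupled sensors through the profile's
#' ground-truth `coupling_*` coefficients, scaled by `coupling_scale`
#' (`coupling_scale = 0` leaves every sensor independent of mood). Outputs
#' are clamped to physically plausible ranges: heart rate to \[40, 180\] bpm,
#' RMSSD to \[5, 200\] ms, speed and light non-negative, calls a non-negative
#' integer (Poisson with mood-modulated log-rate, capped at rate 20).
#'
#' @param latent Tibble from [simulate_latent_mood()].
#' @param profile The matching single-row profile.
#' @param config A [cohort_config()].
#' @return A tibble keyed by `person_id`, `hour_index` with the sensor columns
#'   of the hourly panel.
#' @export
simulate_sensors <- function(latent, profile, config) {
  validate_cohort_config(config)
  n_hours <- nrow(latent)
  weather <- simulate_weather(config, n_hours)
  pidx <- as.integer(sub("^p", "", profile$person_id))
  set.seed(derive_seed(config$seed, 404L, pidx))

  sd_w <- latent_within_sd(config)
  z <- if (sd_w > 0) (latent$latent - profile$mood_intercept) / sd_w else rep(0, n_hours)
  eff <- function(sensor) {
    config$coupling_scale * profile[[paste0("coupling_", sensor)]] * z
  }

  hod <- latent$hour_index %% 24
  awake <- is_awake(hod, profile$wake_hour, config$wake_hours_per_day)

  anchors <- location_anchors()
  # each person's home is their own address; the other anchors are shared
  anchors$lat[1] <- anchors$lat[1] + profile$home_lat_offset
  anchors$lon[1] <- anchors$lon[1] + profile$home_lon_offset
  # asleep -> home; awake: mostly campus during the day, varied otherwise
  anchor_idx <- ifelse(!awake, 1L, apply(
    stats::rmultinom(n_hours, 1, c(0.25, 0.45, 0.1, 0.1, 0.1)), 2, which.max
  ))
  loc <- anchors[anchor_idx, ]
  source_gps <- stats::runif(n_hours) < 0.8
  latitude <- loc$lat + stats::rnorm(n_hours, 0, 0.0008)
  longitude <- loc$lon + stats::rnorm(n_hours, 0, 0.0008)
  location_accuracy <- exp(stats::rnorm(n_hours, ifelse(source_gps, log(10), log(35)), 0.4))
  location_speed <- pmax(0, ifelse(awake, 0.8, 0.05) +
    0.4 * stats::rnorm(n_hours) + 0.4 * eff("location_speed"))

  light_log10 <- ifelse(hod >= 7 & hod <= 19, 2.6, 0.6) +
    0.5 * stats::rnorm(n_hours) + 0.5 * eff("light_level")
  light_level <- round(10^pmin(light_log10, 5), 1)

  hr_mean <- pmin(180, pmax(
    40,
    profile$hr_baseline + 4 * stats::rnorm(n_hours) + 4 * eff("hr_mean")
  ))
  hrv_rmssd <- pmin(200, pmax(
    5,
    profile$rmssd_baseline + 10 * stats::rnorm(n_hours) + 10 * eff("hrv_rmssd")
  ))

  call_rate <- pmin(20, exp(log(0.4) + eff("outgoing_calls"))) *
    ifelse(awake, 1, 0.05)
  outgoing_calls <- stats::rpois(n_hours, call_rate)

  tibble::tibble(
    person_id = profile$person_id,
    hour_index = latent$hour_index,
    awake = awake,
    latitude = latitude,
    longitude = longitude,
    location_accuracy = location_accuracy,
    location_speed = location_speed,
    location_source = ifelse(source_gps, "gps", "wifi"),
    location_type = loc$location_type,
    temperature = weather$temperature,
    humidity = weather$humidity,
    precipitation = weather$precipitation,
    light_level = light_level,
    hr_mean = hr_mean,
    hrv_rmssd = hrv_rmssd,
    outgoing_calls = as.integer(outgoing_calls)
  )
}

# hour-of-day falls in the person's wake window (wrapping midnight)
is_awake <- function(hour_of_day, wake_hour, wake_hours_per_day) {
  rel <- (hour_of_day - wake_hour) %% 24
  rel < wake_hours_per_day
}
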