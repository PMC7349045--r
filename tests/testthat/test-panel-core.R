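test_that("outcome composite is the mean of available items", {
  expect_equal(compute_outcome(0, 0), 0)
  expect_equal(compute_outcome(100, 100), 100)
  expect_equal(compute_outcome(40, 60), mean(c(40, 60)))
  expect_equal(compute_outcome(NA, 80), 80)
  expect_true(is.na(compute_outcome(NA_real_, NA_real_)))
  # symmetry in the two items
  expect_equal(compute_outcome(17, 83), compute_outcome(83, 17))
  expect_error(compute_outcome(120, 10), class = "moodcast_data_error")
})

test_that("rmssd matches hand-computed values and its invariances", {
  expect_equal(rmssd(c(800, 800, 800)), 0)
  expect_equal(rmssd(c(800, 850, 820)), 41.231056256177, tolerance = 1e-10)
  expect_equal(rmssd(rev(c(800, 850, 820))), rmssd(c(800, 850, 820)))
  # translation invariance and linear scaling
  x <- c(812, 795, 840, 820, 810)
  expect_equal(rmssd(x + 100), rmssd(x))
  expect_equal(rmssd(3 * x), 3 * rmssd(x))
  expect_error(rmssd(800), class = "moodcast_insufficient_data")
})

test_that("hourly alignment sums calls, point-reads sensors, attaches mood", {
  events <- tibble::tibble(
    person_id = "p01",
    timestamp = c(14.08, 14.67, 14.98, 13.5, 14.0, 14.4, 14.25),
    stream = c(
      "outgoing_call", "outgoing_call", "outgoing_call",
      "hr_mean", "hr_mean", "hr_mean", "sad"
    ),
    value = c(NA, NA, NA, 68, 71, 75, 40)
  )
  panel <- align_hourly(events)
  h14 <- dplyr::filter(panel, hour_index == 14)
  expect_equal(h14$outgoing_calls, 3L)
  # on-the-hour read: latest sample at or before the hour mark 14
  expect_equal(h14$hr_mean, 71)
  expect_equal(h14$sad, 40)
  # an hour with no events: calls 0, sensors carry forward the latest sample
  h10 <- dplyr::filter(panel, hour_index == 10)
  expect_equal(h10$outgoing_calls, 0L)
  expect_true(is.na(h10$sad))

  # conflicting on-the-hour duplicates name the person and hour
  bad <- dplyr::bind_rows(
    events,
    tibble::tibble(person_id = "p01", timestamp = 14, stream = "hr_mean", value = 90)
  )
  expect_error(align_hourly(bad), "p01.*hour 14", class = "moodcast_data_error")
})

test_that("alignment regroups interleaved persons like a brute-force oracle", {
  set.seed(42)
  n <- 20
  events <- tibble::tibble(
    person_id = sample(c("a", "b"), n, replace = TRUE),
    timestamp = round(runif(n, 0, 6), 2),
    stream = "outgoing_call",
    value = NA_real_
  )
  panel <- align_hourly(events)
  # oracle: plain table() of floor(timestamp) within person
  oracle <- table(events$person_id, floor(events$timestamp))
  for (p in rownames(oracle)) {
    for (h in colnames(oracle)) {
      got <- dplyr::filter(panel, person_id == p, hour_index == as.integer(h))
      expect_equal(got$outgoing_calls, unname(oracle[p, h]))
    }
  }
  # persons are disjoint rows on the shared grid
  expect_equal(
    nrow(panel),
    2 * (max(floor(events$timestamp)) + 1)
  )
})

test_that("panel I/O round trips losslessly, including missingness", {
  co <- small_cohort(seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(co$panel, path)
  back <- read_panel(path)
  expect_equal(
    as.data.frame(back),
    as.data.frame(dplyr::arrange(co$panel, person_id, hour_index)),
    tolerance = 1e-12
  )
  # 31 x 192 grid reads back as 5952 records
  big <- generate_cohort(cohort_config(seed = 22))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(big$panel, path2)
  expect_equal(nrow(read_panel(path2)), 5952)

  # mandatory keys only: everything else missing
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(person_id = "x", hour_index = 0:3), path3)
  minimal <- read_panel(path3)
  expect_equal(nrow(minimal), 4)
  expect_true(all(is.na(minimal$hr_mean)))
  # unknown columns warn; absent keys are a format error
  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    tibble::tibble(person_id = "x", hour_index = 0, mystery = 1), path4
  )
  expect_warning(read_panel(path4), "mystery")
  path5 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(hour_index = 0), path5)
  expect_error(
    suppressWarnings(read_panel(path5)),
    class = "moodcast_format_error"
  )
})

test_that("multiple imputation respects its contracts", {
  expect_error(
    impute_panel(small_cohort()$panel, m = 1),
    class = "moodcast_config_error"
  )

  # complete panel: m identical copies
  complete <- toy_panel()
  imp0 <- impute_panel(complete, m = 3, seed = 1)
  expect_identical(imp0$panels[[1]], imp0$panels[[2]])
  expect_identical(imp0$panels[[2]], imp0$panels[[3]])

  co <- small_cohort(seed = 23)
  imp <- impute_panel(co$panel, m = 3, seed = 2)
  p1 <- imp$panels[[1]]
  # nothing missing in model-input fields afterwards
  expect_false(anyNA(p1[, c(sensor_feature_names(), "sad", "lonely")]))
  # observed cells never altered, across all copies
  for (k in 1:3) {
    for (col in c("hr_mean", "sad", "location_type")) {
      obs <- !is.na(co$panel[[col]])
      expect_identical(imp$panels[[k]][[col]][obs], co$panel[[col]][obs])
    }
  }
  # copies differ where values were imputed
  mis <- is.na(co$panel$hr_mean)
  expect_false(identical(imp$panels[[1]]$hr_mean[mis], imp$panels[[2]]$hr_mean[mis]))
  # categorical imputations stay within the category set
  expect_true(all(p1$location_source %in% c("gps", "wifi")))
  # range contract: imputed values within the person's observed range when
  # that person has >= 3 observations
  counts <- co$panel |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(n = sum(!is.na(hr_mean)))
  for (p in counts$person_id[counts$n >= 3]) {
    obs_rng <- range(co$panel$hr_mean[co$panel$person_id == p], na.rm = TRUE)
    imp_vals <- p1$hr_mean[mis & co$panel$person_id == p]
    expect_true(all(imp_vals >= obs_rng[1] & imp_vals <= obs_rng[2]))
  }
})

test_that("mask-and-recover imputation beats the marginal spread", {
  complete <- generate_cohort(
    cohort_config(n_persons = 8, n_days = 4, compliance_rate = 1,
      wake_hours_per_day = 24, prompt_days = 4, sensor_missing_rate = 0, seed = 31
    )
  )$panel
  set.seed(99)
  masked <- complete
  hit <- runif(nrow(masked)) < 0.10
  masked$temperature[hit] <- NA_real_
  imp <- impute_panel(masked, m = 5, seed = 3)
  avg <- rowMeans(sapply(imp$panels, function(p) p$temperature[hit]))
  rmse <- sqrt(mean((avg - complete$temperature[hit])^2))
  expect_lt(rmse, sd(complete$temperature))
})
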