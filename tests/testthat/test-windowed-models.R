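test_that("rolling windows keep training strictly before the target hour", {
  panel <- toy_panel(n_persons = 3, n_hours = 48)
  win <- build_window(panel, t = 24)
  expect_s3_class(win, "window_spec")
  expect_true(all(win$training$hour_index >= 0 & win$training$hour_index < 24))
  expect_true(all(win$prediction$hour_index == 24))
  expect_lte(nrow(win$training), 3 * 24)
  expect_error(build_window(panel, t = 10), class = "moodcast_config_error")

  # mood missing everywhere in the lookback: a skip signal, not an error
  gap <- panel
  gap$sad[gap$hour_index < 30] <- NA
  gap$lonely[gap$hour_index < 30] <- NA
  expect_true(build_window(gap, t = 30)$skip)

  # rows lacking outcome are excluded from training but predictable
  part <- panel
  part$sad[part$hour_index == 20] <- NA
  part$lonely[part$hour_index == 20] <- NA
  win2 <- build_window(part, t = 24)
  expect_false(any(win2$training$hour_index == 20))
})

test_that("nomothetic stage centers within person and fits strong signal", {
  panel <- toy_panel(n_persons = 3, n_hours = 48, slope = 2, noise = 0)
  dict <- feature_dictionary(panel)
  win <- build_window(panel, t = 24)

  # constant outcome: centered predictions are all ~0
  const <- panel
  const$sad <- 50
  const$lonely <- 50
  win_c <- build_window(const, t = 24)
  fit_c <- fit_nomothetic(win_c, dict, nomothetic_config(rounds = 10), seed = 1)
  expect_equal(stats::predict(fit_c, win_c$prediction), rep(0, 3), tolerance = 1e-6)

  # single strong linear feature, noise-free: training R^2 > 0.9
  fit <- fit_nomothetic(win, dict, nomothetic_config(), seed = 1)
  yhat <- stats::predict(fit, win$training)
  centers <- tapply(win$training$mood, win$training$person_id, mean)
  y_cent <- win$training$mood - centers[win$training$person_id]
  r2 <- 1 - sum((y_cent - yhat)^2) / sum((y_cent - mean(y_cent))^2)
  expect_gt(r2, 0.9)
  # predictions are finite for every prediction row
  expect_true(all(is.finite(stats::predict(fit, win$prediction))))
})

test_that("stacking appends exactly one feature and checks alignment", {
  panel <- toy_panel()
  dict <- feature_dictionary(panel)
  win <- build_window(panel, t = 24)
  preds <- seq_len(nrow(win$training))
  stacked <- augment_features(win$training, preds)
  expect_equal(ncol(stacked), ncol(win$training) + 1)
  expect_equal(
    ncol(cbind(feature_matrix(stacked, dict), stacked$yhat_nomothetic)),
    dict$p + 1
  )
  expect_error(
    augment_features(win$training, preds[-1]),
    class = "moodcast_alignment_error"
  )
  # order independence: shuffling rows with matched predictions preserves content
  idx <- sample(nrow(win$training))
  shuffled <- augment_features(win$training[idx, ], preds[idx])
  expect_equal(
    dplyr::arrange(shuffled, person_id, hour_index),
    dplyr::arrange(stacked, person_id, hour_index)
  )
})

test_that("per-split candidate grid spans [1, p] with three sorted values", {
  expect_equal(mtry_grid(21), c(1, 11, 21))
  expect_equal(mtry_grid(3), c(1, 2, 3))
  g <- mtry_grid(19)
  expect_true(all(diff(g) > 0) && min(g) >= 1 && max(g) <= 19)
})

test_that("weighting degeneracies reduce to pooled and person-only forests", {
  panel <- toy_panel(n_persons = 3, n_hours = 48, noise = 5, seed = 7)
  dict <- feature_dictionary(panel)
  win <- build_window(panel, t = 24)
  stacked <- augment_features(win$training, rep(0, nrow(win$training)))
  cfg <- fast_idio()

  # equal weights: identical to the unweighted pooled forest under one seed
  fit_eq <- fit_idiographic(stacked, "p01", dict,
    weight_scheme(1, 1), cfg,
    seed = 101
  )
  X <- cbind(feature_matrix(stacked, dict), yhat_nomothetic = stacked$yhat_nomothetic)
  oracle_eq <- ranger::ranger(
    x = X, y = stacked$mood, num.trees = cfg$forest_size,
    mtry = fit_eq$best$mtry, splitrule = fit_eq$best$splitrule,
    num.threads = 1, seed = derive_seed(101, 99L)
  )
  newX <- cbind(feature_matrix(win$prediction, dict), yhat_nomothetic = 0)
  colnames(newX) <- colnames(X)
  expect_equal(
    predict(fit_eq, augment_features(win$prediction, rep(0, nrow(win$prediction)))),
    as.numeric(predict(oracle_eq, data = newX, num.threads = 1)$predictions)
  )

  # zero other-weight: identical to the forest fit on the person's rows alone
  fit_solo <- fit_idiographic(stacked, "p01", dict,
    weight_scheme(1, 0), cfg,
    seed = 202
  )
  own <- stacked[stacked$person_id == "p01", ]
  Xo <- cbind(feature_matrix(own, dict), yhat_nomothetic = own$yhat_nomothetic)
  oracle_solo <- ranger::ranger(
    x = Xo, y = own$mood, num.trees = cfg$forest_size,
    mtry = fit_solo$best$mtry, splitrule = fit_solo$best$splitrule,
    num.threads = 1, seed = derive_seed(202, 99L)
  )
  expect_equal(
    predict(fit_solo, augment_features(win$prediction, rep(0, nrow(win$prediction)))),
    as.numeric(predict(oracle_solo, data = newX, num.threads = 1)$predictions)
  )
})

test_that("cv tuning folds stay inside the training window", {
  panel <- toy_panel(n_persons = 4, n_hours = 48, noise = 5, seed = 8)
  dict <- feature_dictionary(panel)
  win <- build_window(panel, t = 30)
  stacked <- augment_features(win$training, rep(0, nrow(win$training)))
  fit <- fit_idiographic(stacked, "p02", dict,
    weight_scheme(), fast_idio(tune_method = "cv"),
    seed = 5
  )
  expect_s3_class(fit, "idiographic_fit")
  expect_true(fit$best$splitrule %in% c("variance", "extratrees"))
  expect_equal(nrow(fit$tuning), 6)
  # the fitted forest saw only hours < t (tuning included): its training
  # size equals the window's row count
  expect_equal(fit$forest$num.samples, nrow(stacked))
})

test_that("stacked dimensionality is constant across windows", {
  co <- small_cohort(seed = 41)
  imp <- impute_panel(co$panel, m = 2, seed = 1)
  dict <- feature_dictionary(imp$panels[[1]])
  widths <- sapply(c(24, 40, 60), function(t) {
    win <- build_window(add_outcome(imp$panels[[1]]), t)
    ncol(feature_matrix(win$training, dict)) + 1
  })
  expect_equal(widths, rep(dict$p + 1, 3))
})

test_that("pipeline ledger obeys the fit-count product contract", {
  co <- small_cohort(seed = 42)
  imp <- impute_panel(co$panel, m = 2, seed = 2)
  # dry run enumerates persons x hours x imputations planned fits
  dry <- run_pipeline(imp, hours = 30:34, dry_run = TRUE)
  expect_equal(nrow(dry$ledger), 5 * 5 * 2)
  expect_true(all(dry$ledger$status == "planned"))
  expect_equal(nrow(dry$records), 0)

  # 3 persons x 5 target hours x 1-of-2 imputations would be 15 fits each
  co3 <- generate_cohort(cohort_config(n_persons = 3, n_days = 3, seed = 43))
  imp3 <- impute_panel(co3$panel, m = 2, seed = 3)
  run3 <- run_pipeline(imp3,
    hours = seq(30, 46, by = 4), seed = 4,
    nomothetic = fast_nomo(), idiographic = fast_idio(), fit_persons = "all"
  )
  expect_equal(sum(run3$ledger$status == "fitted"), 3 * 5 * 2)
  # records only for persons observed at the target hour
  obs <- add_outcome(co3$panel)
  for (i in seq_len(nrow(run3$records))) {
    r <- run3$records[i, ]
    expect_true(!is.na(obs$mood[obs$person_id == r$person_id &
      obs$hour_index == r$hour_index]))
  }
  # records carry both prediction columns, finite
  expect_true(all(is.finite(run3$records$yhat_nomothetic)))
  expect_true(all(is.finite(run3$records$yhat_idiographic)))
})

test_that("future outcomes cannot influence hour-t predictions", {
  cfg <- cohort_config(n_persons = 4, n_days = 3, seed = 44)
  co <- generate_cohort(cfg)
  imp <- impute_panel(co$panel, m = 2, seed = 5)
  t0 <- 40L
  base <- run_pipeline(imp,
    hours = t0, seed = 6,
    nomothetic = fast_nomo(), idiographic = fast_idio(), fit_persons = "observed"
  )
  # corrupt all observed outcomes at hours >= t
  corrupted <- co$panel
  future <- corrupted$hour_index >= t0
  corrupted$sad[future & !is.na(corrupted$sad)] <- 99
  corrupted$lonely[future & !is.na(corrupted$lonely)] <- 99
  imp2 <- impute_panel(corrupted, m = 2, seed = 5)
  after <- run_pipeline(imp2,
    hours = t0, seed = 6,
    nomothetic = fast_nomo(), idiographic = fast_idio(), fit_persons = "observed"
  )
  expect_identical(base$records$yhat_idiographic, after$records$yhat_idiographic)
  expect_identical(base$records$yhat_nomothetic, after$records$yhat_nomothetic)
})
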