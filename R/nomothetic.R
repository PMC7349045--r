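#' Configuration of the pooled (nomothetic) boosting stage
#'
#' The first modelling phase fits a single gradient-boosted tree ensemble on
#' the pooled window, targeting the within-person-centered outcome (each
#' person's training-window mean is subtracted), which operationalises
#' modelling intraindividual variability. Its predictions are never reported
#' directly; they are stacked as one extra feature into the idiographic stage.
#'
#' @param rounds Boosting rounds.
#' @param depth Maximum tree depth.
#' @param learning_rate Shrinkage (eta).
#' @param center_within_person Centre the outcome on each person's
#'   training-window mean (default TRUE); persons absent from the window use
#'   the cohort mean.
#' @return A list of class `nomothetic_config`.
#' @export
nomothetic_config <- function(rounds = 50L, depth = 3L, learning_rate = 0.3,
                              center_within_person = TRUE) {
  if (rounds < 1L) {
    rlang::abort("`rounds` must be >= 1.", class = "moodcast_config_error")
  }
  structure(
    list(
      rounds = as.integer(rounds), depth = as.integer(depth),
      learning_rate = learning_rate,
      center_within_person = isTRUE(center_within_person)
    ),
    class = "nomothetic_config"
  )
}

#' Fit the pooled nomothetic boosting model on one window
#'
#' @param window A [build_window()] result with a non-empty training set.
#' @param dict A [feature_dictionary()].
#' @param config A [nomothetic_config()].
#' @param seed Integer seed for the boosting fit.
#' @return An object of class `nomothetic_fit` with a [predict()] method that
#'   returns predictions on the centered scale.
#' @export
fit_nomothetic <- function(window, dict, config = nomothetic_config(), seed = 1L) {
  stopifnot(inherits(window, "window_spec"))
  if (window$skip || nrow(window$training) < 2L) {
    rlang::abort("window has fewer than 2 training rows.",
      class = "moodcast_insufficient_data"
    )
  }
  training <- window$training
  centers <- training |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(center = mean(.data$mood), .groups = "drop")
  cohort_center <- mean(training$mood)
  y <- if (config$center_within_person) {
    training$mood - centers$center[match(training$person_id, centers$person_id)]
  } else {
    training$mood
  }
  X <- feature_matrix(training, dict)
  set.seed(seed)
  booster <- xgboost::xgb.train(
    params = list(
      max_depth = config$depth, eta = config$learning_rate,
      objective = "reg:squarederror", nthread = 1, seed = seed
    ),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = config$rounds, verbose = 0
  )
  structure(
    list(
      booster = booster, dict = dict, config = config,
      centers = centers, cohort_center = cohort_center
    ),
    class = "nomothetic_fit"
  )
}

#' @describeIn fit_nomothetic Predict centered-scale outcomes for panel rows.
#' @param object A `nomothetic_fit`.
#' @param rows Panel rows to predict for.
#' @param ... Unused.
#' @export
predict.nomothetic_fit <- function(object, rows, ...) {
  X <- feature_matrix(rows, object$dict)
  as.numeric(stats::predict(object$booster, xgboost::xgb.DMatrix(X)))
}

# out-of-fold nomothetic predictions for the training rows themselves
# (person-blocked folds), so the stacked feature is out-of-sample
oof_nomothetic <- function(window, dict, config, seed, n_folds = 3L) {
  training <- window$training
  persons <- unique(training$person_id)
  if (length(persons) < 2L || nrow(training) < 2L * n_folds) {
    fit <- fit_nomothetic(window, dict, config, seed)
    return(stats::predict(fit, training))
  }
  set.seed(derive_seed(seed, 11L))
  fold_of <- sample(rep_len(seq_len(n_folds), length(persons)))
  names(fold_of) <- persons
  preds <- rep(NA_real_, nrow(training))
  for (f in seq_len(n_folds)) {
    hold <- fold_of[training$person_id] == f
    if (!any(hold) || sum(!hold) < 2L) next
    sub <- window
    sub$training <- training[!hold, , drop = FALSE]
    fit <- fit_nomothetic(sub, dict, config, derive_seed(seed, 12L, f))
    preds[hold] <- stats::predict(fit, training[hold, , drop = FALSE])
  }
  if (anyNA(preds)) {
    fit <- fit_nomothetic(window, dict, config, seed)
    preds[is.na(preds)] <- stats::predict(fit, training[is.na(preds), , drop = FALSE])
  }
  preds
}

#' Stack nomothetic predictions onto a feature set
#'
#' Appends the pooled model's prediction as one extra column
#' (`yhat_nomothetic`), so the stacked design has exactly `p + 1` columns.
#'
#' @param rows Panel rows.
#' @param nomothetic_predictions Numeric vector, one prediction per row.
#' @return `rows` with a `yhat_nomothetic` column.
#' @export
augment_features <- function(rows, nomothetic_predictions) {
  if (length(nomothetic_predictions) != nrow(rows)) {
    rlang::abort("one nomothetic prediction is required per row.",
      class = "moodcast_alignment_error"
    )
  }
  dplyr::mutate(rows, yhat_nomothetic = as.numeric(nomothetic_predictions))
}
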