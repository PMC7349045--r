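#' Build a rolling training window for one target hour
#'
#' For target hour `t`, the training set is every person-hour with
#' `hour_index` in the half-open interval `[t - lookback, t)` and a
#' non-missing depressed-mood outcome; the prediction set is every person-hour
#' at exactly `t`. Every training row therefore strictly precedes the target
#' hour, so temporal direction is never reversed. An empty training set is a
#' skip signal (the window object reports it), not an error.
#'
#' @param panel A panel tibble (a `mood` column is added if absent).
#' @param t Target hour index (`t >= lookback`).
#' @param lookback Window length in hours (default 24).
#' @return A list of class `window_spec` with `t`, `lookback`, `training`,
#'   `prediction` and `skip` (TRUE when no training rows exist).
#' @export
build_window <- function(panel, t, lookback = 24L) {
  if (t < lookback) {
    rlang::abort("target hour must be at least `lookback`.",
      class = "moodcast_config_error"
    )
  }
  if (!"mood" %in% names(panel)) panel <- add_outcome(panel)
  training <- dplyr::filter(
    panel,
    .data$hour_index >= t - lookback, .data$hour_index < t, !is.na(.data$mood)
  )
  prediction <- dplyr::filter(panel, .data$hour_index == t)
  structure(
    list(
      t = as.integer(t), lookback = as.integer(lookback),
      training = training, prediction = prediction,
      skip = nrow(training) == 0L
    ),
    class = "window_spec"
  )
}

#' Person-weighting scheme for the idiographic stage
#'
#' The idiographic models are pooled fits in which the focal person's rows are
#' weighted `target_weight` (default 1) and everyone else's `other_weight`
#' (default 0.2), so training strongly favours the person's own patterns while
#' staying informed by the cohort.
#'
#' @param target_weight Weight on the focal person's rows (> 0).
#' @param other_weight Weight on all other rows (>= 0; 0 reduces to a
#'   person-only model).
#' @return A list of class `weight_scheme`.
#' @export
weight_scheme <- function(target_weight = 1, other_weight = 0.2) {
  if (target_weight <= 0 || other_weight < 0 || other_weight > target_weight) {
    rlang::abort(
      "need target_weight > 0 and 0 <= other_weight <= target_weight.",
      class = "moodcast_config_error"
    )
  }
  structure(
    list(target_weight = target_weight, other_weight = other_weight),
    class = "weight_scheme"
  )
}
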