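#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-person correlation table of an evaluation
#'
#' @param x A [evaluate_predictions()] result.
#' @param ... Unused.
#' @return Tibble with one row per person (`person_id`, `r`, `ci_low`,
#'   `ci_high`, `n`, `note`).
#' @method tidy mood_evaluation
#' @export
tidy.mood_evaluation <- function(x, ...) {
  x$per_person
}

#' One-row summary of an evaluation
#'
#' @param x A [evaluate_predictions()] result.
#' @param ... Unused.
#' @return One-row tibble with the pooled correlation and the Fisher-z
#'   average of the per-person correlations.
#' @method glance mood_evaluation
#' @export
glance.mood_evaluation <- function(x, ...) {
  tibble::tibble(
    r = x$pooled$r, ci_low = x$pooled$ci_low, ci_high = x$pooled$ci_high,
    n_pairs = x$pooled$n,
    average_r = x$average$average_r,
    average_ci_low = x$average$ci_low, average_ci_high = x$average$ci_high,
    n_persons = x$average$n_persons
  )
}

#' Tidy the interaction coefficients of a race-moderation test
#'
#' @param x A [race_moderation_test()] result.
#' @param ... Unused.
#' @method tidy moderation_result
#' @export
tidy.moderation_result <- function(x, ...) {
  if (!x$testable || is.null(x$coefficients)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' One-row summary of a race-moderation test
#'
#' @param x A [race_moderation_test()] result.
#' @param ... Unused.
#' @method glance moderation_result
#' @export
glance.moderation_result <- function(x, ...) {
  tibble::tibble(
    testable = x$testable, f_stat = x$f_stat, df_num = x$df_num,
    df_den = x$df_den, p_value = x$p_value
  )
}

#' One-row summary of a lagged-outcome control test
#'
#' @param x A [lagged_outcome_test()] result.
#' @param ... Unused.
#' @method glance lagged_result
#' @export
glance.lagged_result <- function(x, ...) {
  tibble::tibble(
    beta1 = x$beta1, se = x$se, t_stat = x$t_stat, df = x$df,
    p_value = x$p_value, n = x$n
  )
}

#' Tidy a pipeline run into its prediction records
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @method tidy mood_predictions
#' @export
tidy.mood_predictions <- function(x, ...) {
  x$records
}

#' One-row summary of a pipeline run
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @method glance mood_predictions
#' @export
glance.mood_predictions <- function(x, ...) {
  tibble::tibble(
    n_records = nrow(x$records),
    n_fits = sum(x$ledger$status == "fitted"),
    n_planned = sum(x$ledger$status == "planned"),
    n_skipped = sum(grepl("^skipped", x$ledger$status)),
    m = x$m, n_hours = length(x$hours)
  )
}
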