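#' Pool prediction records across imputations
#'
#' Averages the predictions (and, where they were imputed, the observed
#' values — here observed outcomes are never imputed, so they pass through)
#' over the `m` imputed copies, leaving one row per (person, observed hour).
#'
#' @param records Prediction records from [run_pipeline()].
#' @return Tibble with one pooled row per (person, hour).
#' @export
pool_imputations <- function(records) {
  counts <- records |>
    dplyr::count(.data$person_id, .data$hour_index)
  if (dplyr::n_distinct(counts$n) > 1L) {
    rlang::abort("inconsistent number of imputations across (person, hour) cells.",
      class = "moodcast_alignment_error"
    )
  }
  records |>
    dplyr::group_by(.data$person_id, .data$hour_index) |>
    dplyr::summarise(
      y_observed = mean(.data$y_observed),
      yhat_nomothetic = mean(.data$yhat_nomothetic),
      yhat_idiographic = mean(.data$yhat_idiographic),
      m = dplyr::n(),
      .groups = "drop"
    )
}

# Fisher-z confidence interval for a single Pearson correlation
fisher_ci <- function(r, n, level = 0.95) {
  if (n < 3) {
    return(c(NA_real_, NA_real_))
  }
  if (n == 3) {
    return(c(-1, 1)) # z interval has infinite width at n = 3
  }
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Pearson correlation between observed and predicted mood, with CI
#'
#' Computes the pooled predicted-versus-observed Pearson correlation and its
#' 95% confidence interval via the Fisher z transform
#' (`z +/- 1.96 / sqrt(n - 3)`, back-transformed). A correlation over fewer
#' than 3 pairs, or with zero variance in either vector, is signalled as
#' undefined (an `NA` result with a classed warning), never as propagated
#' `NaN`.
#'
#' @param pairs Tibble of pooled pairs (see [pool_imputations()]).
#' @param observed,predicted Column names of the two vectors.
#' @return One-row tibble: `r`, `ci_low`, `ci_high`, `n`.
#' @export
pooled_correlation <- function(pairs, observed = "y_observed",
                               predicted = "yhat_idiographic") {
  y <- pairs[[observed]]
  yhat <- pairs[[predicted]]
  ok <- !is.na(y) & !is.na(yhat)
  y <- y[ok]
  yhat <- yhat[ok]
  n <- length(y)
  if (n < 3L || stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    rlang::warn(
      if (n < 3L) "fewer than 3 pairs: correlation undefined." else
        "zero variance: correlation undefined.",
      class = "moodcast_undefined_correlation"
    )
    return(tibble::tibble(
      r = NA_real_, ci_low = NA_real_, ci_high = NA_real_, n = n
    ))
  }
  r <- stats::cor(y, yhat)
  ci <- if (abs(r) < 1) fisher_ci(r, n) else c(r, r)
  tibble::tibble(r = r, ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Per-person predicted-versus-observed correlations
#'
#' Pearson correlation (with the same Fisher-z CI as [pooled_correlation()])
#' restricted to each person's pairs, quantifying how well the models track
#' intraindividual mood variability. Persons with fewer than 3 pairs or
#' degenerate variance are flagged in `note` rather than dropped silently.
#'
#' @inheritParams pooled_correlation
#' @return Tibble with one row per person: `person_id`, `r`, `ci_low`,
#'   `ci_high`, `n`, `note` (`"ok"`, `"insufficient_data"` or `"undefined"`).
#' @export
person_correlations <- function(pairs, observed = "y_observed",
                                predicted = "yhat_idiographic") {
  pairs |>
    dplyr::group_by(.data$person_id) |>
    dplyr::group_modify(function(d, key) {
      y <- d[[observed]]
      yhat <- d[[predicted]]
      ok <- !is.na(y) & !is.na(yhat)
      y <- y[ok]
      yhat <- yhat[ok]
      n <- length(y)
      if (n < 3L) {
        return(tibble::tibble(
          r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          n = n, note = "insufficient_data"
        ))
      }
      if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
        return(tibble::tibble(
          r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          n = n, note = "undefined"
        ))
      }
      r <- stats::cor(y, yhat)
      ci <- if (abs(r) < 1) fisher_ci(r, n) else c(r, r)
      tibble::tibble(r = r, ci_low = ci[1], ci_high = ci[2], n = n, note = "ok")
    }) |>
    dplyr::ungroup()
}

#' Fisher-z average of per-person correlations
#'
#' Correlations do not combine linearly, so the across-person average is
#' computed by transforming each r to Fisher's z (`atanh`), averaging on the
#' z scale, and back-transforming (`tanh`). The confidence interval is a
#' t interval on the z scale with `persons - 1` degrees of freedom, also
#' back-transformed. Any |r| = 1 is clamped to 1 - 1e-7 with a warning
#' (atanh is infinite there); `NA` correlations are excluded.
#'
#' @param rs Numeric vector of per-person correlations.
#' @param level Confidence level.
#' @return One-row tibble: `average_r`, `ci_low`, `ci_high`, `n_persons`.
#' @examples
#' fisher_average(c(0.2, 0.6)) # about 0.42
#' @export
fisher_average <- function(rs, level = 0.95) {
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0L) {
    return(tibble::tibble(
      average_r = NA_real_, ci_low = NA_real_, ci_high = NA_real_, n_persons = 0L
    ))
  }
  if (any(abs(rs) >= 1)) {
    rlang::warn("|r| = 1 clamped to 1 - 1e-7 before Fisher transform.",
      class = "moodcast_clamped_correlation"
    )
    rs <- pmin(1 - 1e-7, pmax(-1 + 1e-7, rs))
  }
  z <- atanh(rs)
  n <- length(z)
  mz <- mean(z)
  if (n < 2L || stats::sd(z) == 0) {
    ci <- c(mz, mz)
  } else {
    half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(z) / sqrt(n)
    ci <- c(mz - half, mz + half)
  }
  tibble::tibble(
    average_r = tanh(mz), ci_low = tanh(ci[1]), ci_high = tanh(ci[2]),
    n_persons = n
  )
}

#' Summarise out-of-sample agreement for a pipeline run
#'
#' Pools the prediction records across imputations, then computes the pooled
#' predicted-versus-observed correlation, the per-person correlation table,
#' and their Fisher-z average.
#'
#' @param predictions A [run_pipeline()] result (or its `records` tibble).
#' @param predicted Which prediction column to evaluate
#'   (`"yhat_idiographic"` or `"yhat_nomothetic"`).
#' @return Object of class `mood_evaluation`: list with `pooled`,
#'   `per_person`, `average` and the pooled `pairs`.
#' @export
evaluate_predictions <- function(predictions, predicted = "yhat_idiographic") {
  records <- if (inherits(predictions, "mood_predictions")) {
    predictions$records
  } else {
    predictions
  }
  pairs <- pool_imputations(records)
  per_person <- person_correlations(pairs, predicted = predicted)
  structure(
    list(
      pooled = pooled_correlation(pairs, predicted = predicted),
      per_person = per_person,
      average = fisher_average(per_person$r),
      pairs = pairs,
      predicted = predicted
    ),
    class = "mood_evaluation"
  )
}

#' @export
print.mood_evaluation <- function(x, ...) {
  cat(sprintf(
    "<mood_evaluation> pooled r = %.3f [%.3f, %.3f] (n = %d); Fisher-average r = %.3f [%.3f, %.3f] over %d persons\n",
    x$pooled$r, x$pooled$ci_low, x$pooled$ci_high, x$pooled$n,
    x$average$average_r, x$average$ci_low, x$average$ci_high,
    x$average$n_persons
  ))
  invisible(x)
}
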