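#' Test whether predictive performance is moderated by race
#'
#' Fits the linear mixed model
#' `outcome ~ prediction * race + (1 | person)` by REML and reports the joint
#' F test (Satterthwaite denominator degrees of freedom, so fractional df are
#' expected) on all prediction-by-race interaction terms. A significant
#' interaction would mean the prediction-outcome slope differs across racial
#' groups. The reference race level is the most frequent category. With a
#' single race level, or fewer than 2 persons in every non-reference level,
#' the moderation is not testable and is signalled as such.
#'
#' @param pairs Pooled pairs from [pool_imputations()] (needs `person_id`,
#'   `y_observed` and the prediction column).
#' @param profiles Profile tibble with `person_id` and `race_group`.
#' @param predicted Prediction column name.
#' @param random_intercept `FALSE` drops the person random intercept and fits
#'   ordinary least squares (the mixed model's boundary case).
#' @return Object of class `moderation_result`: list with `testable`,
#'   `f_stat`, `df_num`, `df_den`, `p_value`, `coefficients` (interaction
#'   terms) and the fitted model.
#' @export
race_moderation_test <- function(pairs, profiles, predicted = "yhat_idiographic",
                                 random_intercept = TRUE) {
  d <- pairs |>
    dplyr::inner_join(
      dplyr::select(profiles, "person_id", "race_group"),
      by = "person_id"
    ) |>
    dplyr::mutate(prediction = .data[[predicted]]) |>
    dplyr::filter(!is.na(.data$y_observed), !is.na(.data$prediction))
  level_persons <- d |>
    dplyr::distinct(.data$person_id, .data$race_group) |>
    dplyr::count(.data$race_group)
  if (nrow(level_persons) < 2L || sum(level_persons$n >= 2L) < 2L) {
    return(structure(
      list(
        testable = FALSE, f_stat = NA_real_, df_num = NA_real_,
        df_den = NA_real_, p_value = NA_real_, coefficients = NULL,
        model = NULL
      ),
      class = "moderation_result"
    ))
  }
  ref <- level_persons$race_group[which.max(level_persons$n)]
  d$race_group <- stats::relevel(factor(d$race_group), ref = ref)

  if (random_intercept) {
    fit <- lmerTest::lmer(
      y_observed ~ prediction * race_group + (1 | person_id),
      data = d, REML = TRUE
    )
    an <- stats::anova(fit, type = 3)
    row <- an["prediction:race_group", ]
    f_stat <- row[["F value"]]
    df_num <- row[["NumDF"]]
    df_den <- row[["DenDF"]]
    p_value <- row[["Pr(>F)"]]
    coefs <- lme4::fixef(fit)
  } else {
    full <- stats::lm(y_observed ~ prediction * race_group, data = d)
    reduced <- stats::lm(y_observed ~ prediction + race_group, data = d)
    an <- stats::anova(reduced, full)
    f_stat <- an$F[2]
    df_num <- an$Df[2]
    df_den <- an$Res.Df[2]
    p_value <- an$`Pr(>F)`[2]
    coefs <- stats::coef(full)
  }
  inter <- coefs[grepl("^prediction:race_group", names(coefs))]
  structure(
    list(
      testable = TRUE, f_stat = as.numeric(f_stat), df_num = as.numeric(df_num),
      df_den = as.numeric(df_den), p_value = as.numeric(p_value),
      coefficients = inter, model = if (random_intercept) fit else full
    ),
    class = "moderation_result"
  )
}

#' @export
print.moderation_result <- function(x, ...) {
  if (!x$testable) {
    cat("<moderation_result> not testable (need >= 2 race levels with >= 2 persons)\n")
  } else {
    cat(sprintf(
      "<moderation_result> F(%g, %.1f) = %.3f, p = %.3f\n",
      x$df_num, x$df_den, x$f_stat, x$p_value
    ))
  }
  invisible(x)
}

#' Attach the previous-hour outcome to pooled pairs
#'
#' The lag is strictly the hour before (`t - 1`): the observed outcome when
#' the previous hour was answered, else the imputation-averaged imputed
#' outcome when an imputed set is supplied, else missing. Rows with no
#' defined lag are dropped by [lagged_outcome_test()].
#'
#' @param pairs Pooled pairs from [pool_imputations()].
#' @param imputed Optional [impute_panel()] result used to fill unobserved
#'   previous-hour outcomes with imputation-averaged values.
#' @return `pairs` with a `lag_outcome` column.
#' @export
add_lagged_outcome <- function(pairs, imputed = NULL) {
  lag_hours <- tibble::tibble(
    person_id = pairs$person_id, hour_index = pairs$hour_index - 1L
  )
  if (!is.null(imputed)) {
    stopifnot(inherits(imputed, "mood_imputed_set"))
    avg <- purrr::map(imputed$panels, add_outcome) |>
      purrr::list_rbind() |>
      dplyr::group_by(.data$person_id, .data$hour_index) |>
      dplyr::summarise(mood_imp = mean(.data$mood), .groups = "drop")
    obs <- add_outcome(imputed$observed) |>
      dplyr::select("person_id", "hour_index", mood_obs = "mood")
    lut <- dplyr::left_join(avg, obs, by = c("person_id", "hour_index")) |>
      dplyr::mutate(mood = dplyr::coalesce(.data$mood_obs, .data$mood_imp))
  } else {
    lut <- dplyr::select(pairs, "person_id", "hour_index", mood = "y_observed")
  }
  pairs$lag_outcome <- lut$mood[match(
    paste(lag_hours$person_id, lag_hours$hour_index),
    paste(lut$person_id, lut$hour_index)
  )]
  pairs
}

#' Test prediction-outcome association controlling for the lagged outcome
#'
#' Fits `outcome ~ prediction + lagged_outcome + (1 | person)` by REML and
#' reports the prediction slope with its Satterthwaite-approximate t test —
#' the check that the models are not merely carrying the last observed mood
#' forward in time. Predictions nearly collinear with the lag (|r| > 0.999)
#' raise a classed warning because the slope is then not interpretable.
#'
#' @param pairs Pooled pairs carrying a `lag_outcome` column (see
#'   [add_lagged_outcome()]).
#' @param predicted Prediction column name.
#' @param random_intercept `FALSE` fits ordinary least squares instead.
#' @return Object of class `lagged_result`: list with `beta1`, `se`, `t_stat`,
#'   `df`, `p_value`, `n` and the fitted model.
#' @export
lagged_outcome_test <- function(pairs, predicted = "yhat_idiographic",
                                random_intercept = TRUE) {
  if (!"lag_outcome" %in% names(pairs)) {
    rlang::abort("pairs lack `lag_outcome`; see add_lagged_outcome().",
      class = "moodcast_alignment_error"
    )
  }
  d <- pairs |>
    dplyr::mutate(prediction = .data[[predicted]]) |>
    dplyr::filter(
      !is.na(.data$y_observed), !is.na(.data$prediction),
      !is.na(.data$lag_outcome)
    )
  if (nrow(d) < 4L) {
    rlang::abort("no (or too few) rows with a defined lagged outcome.",
      class = "moodcast_insufficient_data"
    )
  }
  if (stats::sd(d$prediction) > 0 && stats::sd(d$lag_outcome) > 0 &&
    abs(stats::cor(d$prediction, d$lag_outcome)) > 0.999) {
    rlang::warn(
      "prediction and lagged outcome are collinear; slope not interpretable.",
      class = "moodcast_collinearity"
    )
  }
  if (random_intercept) {
    fit <- lmerTest::lmer(
      y_observed ~ prediction + lag_outcome + (1 | person_id),
      data = d, REML = TRUE
    )
    sm <- stats::coef(summary(fit))["prediction", ]
    out <- list(
      beta1 = sm[["Estimate"]], se = sm[["Std. Error"]], t_stat = sm[["t value"]],
      df = sm[["df"]], p_value = sm[["Pr(>|t|)"]], n = nrow(d), model = fit
    )
  } else {
    fit <- stats::lm(y_observed ~ prediction + lag_outcome, data = d)
    sm <- stats::coef(summary(fit))["prediction", ]
    out <- list(
      beta1 = sm[["Estimate"]], se = sm[["Std. Error"]], t_stat = sm[["t value"]],
      df = fit$df.residual, p_value = sm[["Pr(>|t|)"]], n = nrow(d), model = fit
    )
  }
  structure(out, class = "lagged_result")
}

#' @export
print.lagged_result <- function(x, ...) {
  cat(sprintf(
    "<lagged_result> beta1 = %.3f, SE = %.3f, t(%.1f) = %.3f, p = %.3g\n",
    x$beta1, x$se, x$df, x$t_stat, x$p_value
  ))
  invisible(x)
}
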