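#' Forest plot of per-person predicted-versus-observed correlations
#'
#' One dot per person with its 95% CI, and a dotted vertical line at the
#' Fisher-z average of the correlations.
#'
#' @param object A [evaluate_predictions()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mood_evaluation
#' @export
autoplot.mood_evaluation <- function(object, ...) {
  d <- dplyr::filter(object$per_person, !is.na(.data$r)) |>
    dplyr::arrange(.data$r) |>
    dplyr::mutate(person_id = factor(.data$person_id, levels = .data$person_id))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$person_id))
  if (!is.na(object$average$average_r)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$average$average_r, linetype = "dotted"
    )
  }
  p +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "predicted vs observed correlation (r)", y = NULL,
      title = "Per-person out-of-sample correlations",
      subtitle = sprintf(
        "Fisher-z average r = %.3f [%.3f, %.3f]",
        object$average$average_r, object$average$ci_low, object$average$ci_high
      )
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Observed and predicted hourly mood trajectories per person
#'
#' @param pairs Pooled pairs from [pool_imputations()].
#' @param persons Optional subset of person ids to plot.
#' @param predicted Prediction column to draw.
#' @return A ggplot object, faceted by person.
#' @export
plot_trajectories <- function(pairs, persons = NULL,
                              predicted = "yhat_idiographic") {
  if (!is.null(persons)) {
    pairs <- dplyr::filter(pairs, .data$person_id %in% persons)
  }
  long <- pairs |>
    dplyr::select("person_id", "hour_index",
      observed = "y_observed", predicted = dplyr::all_of(predicted)
    ) |>
    tidyr::pivot_longer(c("observed", "predicted"),
      names_to = "series", values_to = "mood"
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$hour_index, y = .data$mood, colour = .data$series
  )) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~person_id, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(observed = "firebrick", predicted = "steelblue")) +
    ggplot2::labs(
      x = "hour since cohort start", y = "depressed mood (0-100)",
      colour = NULL, title = "Observed vs predicted hourly depressed mood"
    ) +
    ggplot2::theme_minimal()
}
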