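#' Multiple imputation of an hourly panel by chained equations
#'
#' Produces `m` completed copies of the panel using iterative conditional
#' draws ("chained equations"): each incomplete variable is regressed on the
#' other (currently completed) model-input fields, person identity, and
#' sine/cosine of hour-of-day, and its missing cells are redrawn from the
#' predictive distribution (normal draws around the regression prediction).
#' Numeric draws are clamped to the person's observed range when the person
#' has at least 3 observations of that variable, and to the cohort's observed
#' range otherwise, so imputations never leave the plausible range.
#' Categorical fields (`location_source`, `location_type`) are drawn from the
#' person's (else cohort's) observed category frequencies. Observed cells are
#' never altered, and with nothing missing the `m` copies are identical.
#'
#' @param panel A panel tibble (aligned, one row per person-hour).
#' @param m Number of completed copies (at least 2 — multiple imputation
#'   requires multiplicity).
#' @param seed Integer seed; copy `k` uses a child seed derived from it.
#' @param n_sweeps Chained-equation sweeps per copy.
#' @return An object of class `mood_imputed_set`: list with `panels` (list of
#'   `m` completed tibbles), `m`, `imputation_seed`, and `observed` (the input
#'   panel, which carries the observed-data mask).
#' @export
impute_panel <- function(panel, m = 5L, seed = 1L, n_sweeps = 3L) {
  if (m < 2L) {
    rlang::abort("multiple imputation requires m >= 2 completed copies.",
      class = "moodcast_config_error"
    )
  }
  numeric_vars <- c(
    "latitude", "longitude", "location_accuracy", "location_speed",
    "temperature", "humidity", "precipitation", "light_level",
    "hr_mean", "hrv_rmssd", "outgoing_calls", "sad", "lonely"
  )
  cat_vars <- c("location_source", "location_type")
  all_missing <- c(numeric_vars, cat_vars)[vapply(
    c(numeric_vars, cat_vars), function(v) all(is.na(panel[[v]])), logical(1)
  )]
  if (length(all_missing)) {
    rlang::warn(paste0(
      "variables with no observed values left unimputed: ",
      paste(all_missing, collapse = ", ")
    ))
    numeric_vars <- setdiff(numeric_vars, all_missing)
    cat_vars <- setdiff(cat_vars, all_missing)
  }
  panels <- purrr::map(seq_len(m), function(k) {
    set.seed(derive_seed(seed, 707L, k))
    impute_one(panel, numeric_vars, cat_vars, n_sweeps)
  })
  structure(
    list(panels = panels, m = as.integer(m), imputation_seed = as.integer(seed),
      observed = panel),
    class = "mood_imputed_set"
  )
}

# one completed copy under the current RNG state
impute_one <- function(panel, numeric_vars, cat_vars, n_sweeps) {
  completed <- panel
  miss <- purrr::map(c(numeric_vars, cat_vars), ~ is.na(panel[[.x]]))
  names(miss) <- c(numeric_vars, cat_vars)
  if (!any(unlist(miss))) {
    return(completed)
  }
  person <- factor(panel$person_id)
  hod <- panel$hour_index %% 24
  base_design <- cbind(
    sin_h = sin(2 * pi * hod / 24), cos_h = cos(2 * pi * hod / 24),
    if (nlevels(person) > 1) stats::model.matrix(~person)[, -1, drop = FALSE]
  )

  # clamp bounds: person range when >= 3 person-observations, else cohort range
  bounds <- purrr::map(numeric_vars, function(v) {
    obs <- !miss[[v]]
    coh <- range(panel[[v]][obs])
    per <- dplyr::tibble(person_id = panel$person_id, x = panel[[v]], obs = obs) |>
      dplyr::group_by(.data$person_id) |>
      dplyr::summarise(
        n = sum(.data$obs),
        lo = if (sum(.data$obs) >= 3) min(.data$x[.data$obs]) else coh[1],
        hi = if (sum(.data$obs) >= 3) max(.data$x[.data$obs]) else coh[2],
        .groups = "drop"
      )
    idx <- match(panel$person_id, per$person_id)
    list(lo = per$lo[idx], hi = per$hi[idx])
  })
  names(bounds) <- numeric_vars

  # initialise by hot-deck draws from person (else cohort) observed values
  for (v in c(numeric_vars, cat_vars)) {
    mi <- miss[[v]]
    if (!any(mi)) next
    completed[[v]] <- hot_deck_fill(completed[[v]], panel$person_id, mi)
    if (v %in% numeric_vars) {
      completed[[v]][mi] <- pmin(
        bounds[[v]]$hi[mi],
        pmax(bounds[[v]]$lo[mi], completed[[v]][mi])
      )
    }
  }

  # sensors are imputed from sensors only (plus person and hour-of-day);
  # the mood items come last and may draw on the sensors. Mood therefore
  # never feeds sensor imputations, so models trained on imputed sensors
  # but observed moods cannot leak future outcomes backwards in time.
  mood_vars <- intersect(c("sad", "lonely"), numeric_vars)
  sensor_vars <- setdiff(numeric_vars, mood_vars)
  order_vars <- c(
    sensor_vars[order(vapply(sensor_vars, function(v) sum(miss[[v]]), numeric(1)))],
    mood_vars
  )
  for (s in seq_len(n_sweeps)) {
    for (v in order_vars) {
      mi <- miss[[v]]
      if (!any(mi)) next
      others <- if (v %in% mood_vars) {
        setdiff(numeric_vars, v)
      } else {
        setdiff(sensor_vars, v)
      }
      X <- cbind(1, base_design, as.matrix(dplyr::select(
        completed, dplyr::all_of(others)
      )))
      storage.mode(X) <- "double"
      y <- as.numeric(completed[[v]])
      fit <- stats::lm.fit(X[!mi, , drop = FALSE], y[!mi])
      keep <- !is.na(fit$coefficients)
      pred <- X[mi, keep, drop = FALSE] %*% fit$coefficients[keep]
      dfres <- max(1, sum(!mi) - sum(keep))
      sigma <- sqrt(sum(fit$residuals^2) / dfres)
      draw <- pred + stats::rnorm(sum(mi), 0, sigma)
      draw <- pmin(bounds[[v]]$hi[mi], pmax(bounds[[v]]$lo[mi], draw))
      if (v == "outgoing_calls") draw <- round(draw)
      completed[[v]][mi] <- draw
    }
  }
  if ("outgoing_calls" %in% numeric_vars) {
    completed$outgoing_calls <- as.integer(pmax(0, completed$outgoing_calls))
  }
  completed
}

# draw replacements from the person's observed empirical distribution,
# falling back to the cohort's when the person has none
hot_deck_fill <- function(x, person_id, mi) {
  cohort_pool <- x[!is.na(x)]
  for (p in unique(person_id[mi])) {
    rows <- mi & person_id == p
    pool <- x[!is.na(x) & person_id == p]
    if (length(pool) < 3) pool <- cohort_pool
    x[rows] <- sample(pool, sum(rows), replace = TRUE)
  }
  x
}

#' @export
print.mood_imputed_set <- function(x, ...) {
  cat(sprintf(
    "<mood_imputed_set> m = %d copies of a %d-row panel (seed %d)\n",
    x$m, nrow(x$observed), x$imputation_seed
  ))
  invisible(x)
}
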