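#' Column dictionary of the hourly panel
#'
#' @return Character vector of sensor feature columns, in panel order.
#' @export
sensor_feature_names <- function() {
  c(
    "latitude", "longitude", "location_accuracy", "location_speed",
    "location_source", "location_type", "temperature", "humidity",
    "precipitation", "light_level", "hr_mean", "hrv_rmssd", "outgoing_calls"
  )
}

panel_columns <- function() {
  c("person_id", "hour_index", "awake", sensor_feature_names(), "sad", "lonely")
}

#' Align a raw event stream to the hourly panel grid
#'
#' Reduces timestamped events to one row per person-hour, the panel's native
#' resolution (records are stamped on the hour):
#' * `outgoing_call` events are summed within each clock hour `[h, h + 1)`;
#'   an hour with no call events reads 0.
#' * sensor samples are point-read: hour `h` takes the latest sample at or
#'   before the hour mark `h`; hours with no eligible sample are missing.
#' * `sad` / `lonely` mood responses attach to the hour the prompt fell in
#'   (`floor(timestamp)`).
#'
#' Two sensor samples stamped exactly on the same hour with conflicting values
#' are a data error (reported with person and hour).
#'
#' @param events Tibble with columns `person_id`, `timestamp` (hours since
#'   cohort start, fractional allowed), `stream` (a sensor name from
#'   [sensor_feature_names()], `"sad"`, `"lonely"`, or `"outgoing_call"`) and
#'   `value` (`NA` allowed for call events; character for `location_source` /
#'   `location_type`).
#' @return A panel tibble spanning the full persons-by-hours grid (hours 0 to
#'   the last observed hour), with `awake` set to `NA` (unknown from events).
#' @export
align_hourly <- function(events) {
  needed <- c("person_id", "timestamp", "stream", "value")
  if (!all(needed %in% names(events))) {
    rlang::abort("events need columns person_id, timestamp, stream, value.",
      class = "moodcast_format_error"
    )
  }
  known <- c(sensor_feature_names(), "sad", "lonely", "outgoing_call")
  bad <- setdiff(unique(events$stream), known)
  if (length(bad)) {
    rlang::warn(paste0("ignoring unknown streams: ", paste(bad, collapse = ", ")))
    events <- dplyr::filter(events, .data$stream %in% known)
  }
  persons <- sort(unique(events$person_id))
  hours <- 0:max(floor(events$timestamp))
  grid <- tidyr::expand_grid(person_id = persons, hour_index = hours)

  calls <- events |>
    dplyr::filter(.data$stream == "outgoing_call") |>
    dplyr::mutate(hour_index = floor(.data$timestamp)) |>
    dplyr::count(.data$person_id, .data$hour_index, name = "outgoing_calls")

  mood <- events |>
    dplyr::filter(.data$stream %in% c("sad", "lonely")) |>
    dplyr::mutate(hour_index = floor(.data$timestamp)) |>
    dplyr::group_by(.data$person_id, .data$hour_index, .data$stream) |>
    dplyr::summarise(value = as.numeric(dplyr::last(.data$value, order_by = .data$timestamp)),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "stream", values_from = "value")

  sensors <- dplyr::filter(
    events,
    .data$stream %in% setdiff(sensor_feature_names(), "outgoing_calls")
  )
  # conflicting duplicates exactly on an hour mark
  dup <- sensors |>
    dplyr::filter(.data$timestamp == floor(.data$timestamp)) |>
    dplyr::group_by(.data$person_id, .data$timestamp, .data$stream) |>
    dplyr::filter(dplyr::n_distinct(.data$value) > 1) |>
    dplyr::ungroup()
  if (nrow(dup)) {
    d <- dup[1, ]
    rlang::abort(
      sprintf(
        "conflicting on-the-hour samples of %s for person %s at hour %d",
        d$stream, d$person_id, as.integer(d$timestamp)
      ),
      class = "moodcast_data_error"
    )
  }
  sensor_wide <- purrr::map(hours, function(h) {
    sensors |>
      dplyr::filter(.data$timestamp <= h) |>
      dplyr::group_by(.data$person_id, .data$stream) |>
      dplyr::slice_max(.data$timestamp, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::mutate(hour_index = h) |>
      dplyr::select("person_id", "hour_index", "stream", "value")
  }) |>
    purrr::list_rbind() |>
    tidyr::pivot_wider(names_from = "stream", values_from = "value")

  out <- grid |>
    dplyr::left_join(sensor_wide, by = c("person_id", "hour_index")) |>
    dplyr::left_join(calls, by = c("person_id", "hour_index")) |>
    dplyr::left_join(mood, by = c("person_id", "hour_index")) |>
    dplyr::mutate(
      outgoing_calls = as.integer(dplyr::coalesce(.data$outgoing_calls, 0L)),
      awake = NA
    )
  for (col in panel_columns()) {
    if (!col %in% names(out)) {
      out[[col]] <- if (col %in% c("location_source", "location_type")) {
        NA_character_
      } else {
        NA_real_
      }
    }
  }
  numeric_cols <- setdiff(
    c(sensor_feature_names(), "sad", "lonely"),
    c("location_source", "location_type", "outgoing_calls")
  )
  out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(numeric_cols), as.numeric))
  dplyr::select(out, dplyr::all_of(panel_columns())) |>
    dplyr::arrange(.data$person_id, .data$hour_index)
}
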