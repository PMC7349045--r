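#' Read and write hourly panels as long-format CSV
#'
#' The on-disk format is plain delimited text with one person-hour per row and
#' the documented column dictionary (`person_id`, `hour_index`, `awake`, the
#' sensor columns of [sensor_feature_names()], `sad`, `lonely`). Missing cells
#' are empty fields; the round trip is lossless, including missingness.
#' Unknown extra columns are dropped with a warning; a file without the
#' mandatory keys `person_id` and `hour_index` is a format error.
#'
#' @param path File path.
#' @param panel A panel tibble.
#' @return `read_panel()` returns the panel tibble; `write_panel()` invisibly
#'   returns `path`.
#' @export
read_panel <- function(path) {
  parsers <- list(
    person_id = readr::col_character(),
    hour_index = readr::col_integer(),
    awake = readr::col_logical(),
    location_source = readr::col_character(),
    location_type = readr::col_character(),
    outgoing_calls = readr::col_integer()
  )
  hdr <- names(readr::read_csv(path,
    n_max = 0, col_types = readr::cols(), show_col_types = FALSE
  ))
  spec <- do.call(readr::cols, c(
    parsers[intersect(names(parsers), hdr)],
    .default = readr::col_double()
  ))
  panel <- readr::read_csv(path, col_types = spec, progress = FALSE)
  if (!all(c("person_id", "hour_index") %in% names(panel))) {
    rlang::abort("panel file lacks mandatory keys person_id, hour_index.",
      class = "moodcast_format_error"
    )
  }
  extra <- setdiff(names(panel), panel_columns())
  if (length(extra)) {
    rlang::warn(paste0("dropping unknown panel columns: ", paste(extra, collapse = ", ")))
    panel <- dplyr::select(panel, -dplyr::all_of(extra))
  }
  for (col in setdiff(panel_columns(), names(panel))) {
    panel[[col]] <- switch(col,
      awake = NA,
      location_source = NA_character_,
      location_type = NA_character_,
      outgoing_calls = NA_integer_,
      NA_real_
    )
  }
  if (anyDuplicated(panel[c("person_id", "hour_index")])) {
    rlang::abort("duplicate (person_id, hour_index) rows in panel file.",
      class = "moodcast_format_error"
    )
  }
  dplyr::select(panel, dplyr::all_of(panel_columns())) |>
    dplyr::arrange(.data$person_id, .data$hour_index)
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel[, intersect(panel_columns(), names(panel))], path,
    na = "", progress = FALSE
  )
  invisible(path)
}

#' Read and write profile tables
#'
#' @param profiles Profile tibble from [generate_profiles()].
#' @param path File path.
#' @return `read_profiles()` returns the tibble.
#' @export
write_profiles <- function(profiles, path) {
  readr::write_csv(profiles, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      person_id = readr::col_character(),
      race_group = readr::col_character(),
      baseline_dass_d = readr::col_integer(),
      wake_hour = readr::col_integer(),
      bed_hour = readr::col_integer(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
}
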