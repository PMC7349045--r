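#' Depressed-mood composite from the momentary items
#'
#' The momentary outcome is built from the "sad" and "lonely" items (each
#' rated 0-100). The composite is the arithmetic mean of whichever items are
#' present — both items weighted equally — and is missing only when both items
#' are missing. Vectorised over its arguments.
#'
#' @param sad,lonely Numeric vectors on the 0-100 scale (may contain `NA`).
#' @return Numeric vector of composites in \[0, 100\].
#' @examples
#' compute_outcome(40, 60) # 50
#' compute_outcome(NA, 80) # 80
#' @export
compute_outcome <- function(sad, lonely) {
  if (any(c(sad, lonely) < 0 | c(sad, lonely) > 100, na.rm = TRUE)) {
    rlang::abort("mood items must lie in [0, 100].", class = "moodcast_data_error")
  }
  out <- rowMeans(cbind(sad, lonely), na.rm = TRUE)
  out[is.na(sad) & is.na(lonely)] <- NA_real_
  out
}

#' Add the depressed-mood composite column to a panel
#'
#' Pipe-friendly wrapper around [compute_outcome()]: adds (or replaces) a
#' `mood` column.
#'
#' @param panel A panel tibble with `sad` and `lonely` columns.
#' @return The panel with a `mood` column.
#' @export
add_outcome <- function(panel) {
  dplyr::mutate(panel, mood = compute_outcome(.data$sad, .data$lonely))
}

#' Root mean square of successive differences (RMSSD)
#'
#' Time-domain heart-rate-variability measure: the square root of the mean of
#' squared successive differences of inter-beat intervals. Translation of all
#' intervals by a constant leaves it unchanged; scaling all intervals scales
#' it linearly.
#'
#' @param ibis Numeric vector of inter-beat intervals in milliseconds
#'   (at least 2).
#' @return RMSSD in milliseconds.
#' @examples
#' rmssd(c(800, 850, 820)) # sqrt((50^2 + 30^2) / 2)
#' @export
rmssd <- function(ibis) {
  if (length(ibis) < 2L || any(is.na(ibis))) {
    rlang::abort("rmssd needs at least 2 non-missing inter-beat intervals.",
      class = "moodcast_insufficient_data"
    )
  }
  sqrt(mean(diff(ibis)^2))
}
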