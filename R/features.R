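#' Freeze the model feature dictionary for a panel
#'
#' The modelling stages one-hot encode `location_source` and `location_type`
#' against a fixed, sorted category dictionary frozen once at pipeline start,
#' so the design dimensionality `p` is constant across every rolling window.
#' Numeric sensors (including raw latitude/longitude) enter as-is.
#'
#' @param panel A panel tibble (typically the full imputed panel).
#' @return A list of class `feature_dict` with the numeric column names and
#'   the sorted category levels; `p` is its total design width.
#' @export
feature_dictionary <- function(panel) {
  numeric_cols <- c(
    "latitude", "longitude", "location_accuracy", "location_speed",
    "temperature", "humidity", "precipitation", "light_level",
    "hr_mean", "hrv_rmssd", "outgoing_calls"
  )
  src <- sort(unique(stats::na.omit(panel$location_source)))
  typ <- sort(unique(stats::na.omit(panel$location_type)))
  structure(
    list(
      numeric = numeric_cols, location_source = src, location_type = typ,
      p = length(numeric_cols) + length(src) + length(typ)
    ),
    class = "feature_dict"
  )
}

#' Build the numeric design matrix for a set of panel rows
#'
#' @param rows Panel rows (tibble).
#' @param dict A [feature_dictionary()].
#' @return Numeric matrix with `dict$p` columns, rows aligned with `rows`.
#' @export
feature_matrix <- function(rows, dict) {
  stopifnot(inherits(dict, "feature_dict"))
  num <- as.matrix(dplyr::select(rows, dplyr::all_of(dict$numeric)))
  storage.mode(num) <- "double"
  onehot <- function(x, levels, prefix) {
    m <- vapply(levels, function(l) as.double(!is.na(x) & x == l),
      numeric(length(x))
    )
    m <- matrix(m, nrow = length(x), ncol = length(levels))
    colnames(m) <- paste0(prefix, levels)
    m
  }
  cbind(
    num,
    onehot(rows$location_source, dict$location_source, "src_"),
    onehot(rows$location_type, dict$location_type, "type_")
  )
}
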