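#' Score a DASS depression item set
#'
#' The baseline severity measure is the 14-item DASS depression subscale; each
#' item is rated 0-3 over the past week and the score is the plain item sum, so
#' the attainable range is 0 to 42.
#'
#' @param items Integer vector of 14 item ratings, each in 0-3.
#' @return The integer subscale score.
#' @examples
#' dass_depression_score(rep(3L, 14)) # 42
#' @export
dass_depression_score <- function(items) {
  if (length(items) != 14L) {
    rlang::abort("DASS depression subscale has exactly 14 items.",
      class = "moodcast_config_error"
    )
  }
  if (any(is.na(items)) || any(items < 0L | items > 3L) ||
    any(items != round(items))) {
    rlang::abort("DASS items must be integers in 0-3.",
      class = "moodcast_config_error"
    )
  }
  as.integer(sum(items))
}

#' Attainable range of the DASS depression subscale
#'
#' @param n_items Number of items (14 for the depression subscale).
#' @param max_rating Maximum per-item rating (3).
#' @return Length-2 integer vector `c(min, max)`.
#' @examples
#' dass_score_range() # 0 42
#' @export
dass_score_range <- function(n_items = 14L, max_rating = 3L) {
  all_min <- rep(0L, n_items)
  all_max <- rep(as.integer(max_rating), n_items)
  c(sum(all_min), sum(all_max))
}

# draw 14 item ratings (0-3) whose sum equals `total`
draw_dass_items <- function(total) {
  items <- rep(0L, 14L)
  while (sum(items) < total) {
    open <- which(items < 3L)
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    items[pick] <- items[pick] + 1L
  }
  items
}

# severity mix of the emulated sample: 2/31 moderate, 12/31 severe,
# 17/31 extremely severe (DASS-42 depression bands 14-20 / 21-27 / 28-42)
draw_dass_score <- function() {
  band <- sample(3L, 1L, prob = c(2, 12, 17) / 31)
  lims <- switch(band, c(14L, 20L), c(21L, 27L), c(28L, 42L))
  total <- sample(seq(lims[1], lims[2]), 1L)
  dass_depression_score(draw_dass_items(total))
}

#' Generate person profiles for a synthetic cohort
#'
#' Draws one profile per person: race group (from the configured
#' distribution), a baseline DASS depression score built from 14 item ratings
#' (so scores always lie in 0-42), a wake schedule (wake and bed hour of day,
#' constant over enrollment), a latent mood intercept, and the person's
#' ground-truth sensor-mood coupling vector. Couplings are the cohort-level
#' directions plus Normal(0, `coupling_heterogeneity`) person deviations;
#' the first `ceiling(sign_flip_fraction * n_persons)` persons get their whole
#' vector negated.
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per person: `person_id`, `race_group`,
#'   `baseline_dass_d`, `wake_hour`, `bed_hour`, `mood_intercept`, and one
#'   `coupling_*` column per coupled sensor.
#' @export
generate_profiles <- function(config) {
  validate_cohort_config(config)
  set.seed(derive_seed(config$seed, 101L))
  n <- config$n_persons
  race <- sample(names(config$race_distribution), n,
    replace = TRUE, prob = config$race_distribution
  )
  dass <- vapply(seq_len(n), function(i) draw_dass_score(), integer(1))
  wake <- sample(6:10, n, replace = TRUE)
  bed <- (wake + config$wake_hours_per_day) %% 24L
  intercept <- config$intercept_mean +
    config$intercept_dass_slope * (dass - 28) +
    stats::rnorm(n, 0, config$person_intercept_sd)
  base <- coupling_base()
  coup <- matrix(stats::rnorm(n * length(base), 0, config$coupling_heterogeneity),
    nrow = n
  )
  coup <- sweep(coup, 2, base, "+")
  n_flip <- ceiling(config$sign_flip_fraction * n)
  if (n_flip > 0) coup[seq_len(n_flip), ] <- -coup[seq_len(n_flip), ]
  colnames(coup) <- paste0("coupling_", names(base))
  out <- tibble::tibble(
    person_id = sprintf("p%02d", seq_len(n)),
    race_group = race,
    baseline_dass_d = as.integer(dass),
    wake_hour = as.integer(wake),
    bed_hour = as.integer(bed),
    mood_intercept = intercept,
    # stable interindividual sensor differences: people live in different
    # places and have different resting physiology
    home_lat_offset = stats::rnorm(n, 0, config$home_scatter_sd),
    home_lon_offset = stats::rnorm(n, 0, config$home_scatter_sd),
    hr_baseline = stats::rnorm(n, 72, config$hr_baseline_sd),
    rmssd_baseline = stats::rnorm(n, 45, config$rmssd_baseline_sd)
  )
  dplyr::bind_cols(out, tibble::as_tibble(coup))
}
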