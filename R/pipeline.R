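#' Predict one target hour from fitted window models
#'
#' Emits one prediction record per person whose outcome was actually observed
#' at hour `t` (evaluation needs an observation) and who has a fitted
#' idiographic model. Records carry both the stacked nomothetic prediction
#' (centered scale) and the idiographic prediction (raw mood units).
#'
#' @param nomothetic_fit A [fit_nomothetic()] result.
#' @param idiographic_fits Named list (by person) of [fit_idiographic()] fits.
#' @param window The [build_window()] for hour `t`.
#' @param imputation_id Which imputed copy the fits came from.
#' @param observed_mood Tibble `person_id`, `hour_index`, `mood` holding the
#'   *observed* (pre-imputation) outcomes.
#' @return Tibble of prediction records.
#' @export
predict_hour <- function(nomothetic_fit, idiographic_fits, window,
                         imputation_id, observed_mood) {
  rows <- window$prediction
  if (nrow(rows) == 0L) {
    return(empty_records())
  }
  yhat_nomo <- stats::predict(nomothetic_fit, rows)
  rows <- augment_features(rows, yhat_nomo)
  obs_t <- dplyr::filter(observed_mood, .data$hour_index == window$t, !is.na(.data$mood))
  keep <- rows$person_id %in% obs_t$person_id &
    rows$person_id %in% names(idiographic_fits)
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0L) {
    return(empty_records())
  }
  yhat_idio <- purrr::map_dbl(seq_len(nrow(rows)), function(i) {
    stats::predict(idiographic_fits[[rows$person_id[i]]], rows[i, , drop = FALSE])
  })
  tibble::tibble(
    person_id = rows$person_id,
    hour_index = window$t,
    imputation_id = as.integer(imputation_id),
    y_observed = obs_t$mood[match(rows$person_id, obs_t$person_id)],
    yhat_nomothetic = rows$yhat_nomothetic[seq_len(nrow(rows))],
    yhat_idiographic = yhat_idio
  )
}

empty_records <- function() {
  tibble::tibble(
    person_id = character(), hour_index = integer(), imputation_id = integer(),
    y_observed = numeric(), yhat_nomothetic = numeric(),
    yhat_idiographic = numeric()
  )
}

#' Run the full two-phase rolling-window pipeline
#'
#' For every imputed copy and every target hour, fits the pooled nomothetic
#' boosting model on the trailing `lookback`-hour window (training only on
#' rows whose outcome was genuinely observed), stacks its out-of-fold
#' predictions into the design, fits one idiographically weighted forest per
#' person, and predicts the target hour out of sample. Imputed sensor values
#' are used as features; imputed *moods* are never trained on — only observed
#' outcomes enter training windows and evaluation.
#'
#' Every fit is logged in a ledger keyed by (imputation, hour, person) with
#' the chosen hyperparameters; skipped windows are enumerated. In
#' `dry_run = TRUE` mode the ledger of planned fits is produced without
#' training anything. Child seeds are derived per (imputation, hour, person),
#' so results are independent of execution order and any single fit is
#' reproducible in isolation.
#'
#' @param imputed A [impute_panel()] result.
#' @param hours Target hours to predict (default every hour from `lookback`
#'   to the end of the panel).
#' @param lookback Rolling-window length in hours.
#' @param weights A [weight_scheme()].
#' @param nomothetic A [nomothetic_config()].
#' @param idiographic An [idiographic_config()].
#' @param seed Master seed for all model fitting.
#' @param fit_persons `"all"` fits one idiographic model per roster person per
#'   window (the planned-fit contract); `"observed"` fits only persons with an
#'   observed outcome at the target hour — the emitted prediction records are
#'   identical because per-person fits are independent.
#' @param dry_run Emit the planned-fit ledger without fitting.
#' @param jobs Worker processes over target hours (results are identical for
#'   any value because seeds are keyed by coordinates, not execution order).
#' @return An object of class `mood_predictions`: list with `records`
#'   (prediction records), `ledger` (one row per fit or skip) and `m`.
#' @export
run_pipeline <- function(imputed, hours = NULL, lookback = 24L,
                         weights = weight_scheme(),
                         nomothetic = nomothetic_config(),
                         idiographic = idiographic_config(),
                         seed = 1L,
                         fit_persons = c("all", "observed"),
                         dry_run = FALSE, jobs = 1L) {
  stopifnot(inherits(imputed, "mood_imputed_set"))
  fit_persons <- match.arg(fit_persons)
  observed <- add_outcome(imputed$observed)
  max_hour <- max(observed$hour_index)
  if (max_hour < lookback) {
    rlang::abort("panel must span at least lookback + 1 hours.",
      class = "moodcast_config_error"
    )
  }
  if (is.null(hours)) hours <- seq.int(lookback, max_hour)
  persons <- sort(unique(observed$person_id))
  observed_mood <- dplyr::select(observed, "person_id", "hour_index", "mood")

  if (dry_run) {
    ledger <- tidyr::expand_grid(
      imputation_id = seq_len(imputed$m), hour_index = as.integer(hours),
      person_id = persons
    ) |>
      dplyr::mutate(status = "planned", mtry = NA_integer_, splitrule = NA_character_,
        n_train = NA_integer_
      )
    return(structure(
      list(records = empty_records(), ledger = ledger, m = imputed$m,
        hours = as.integer(hours), dry_run = TRUE),
      class = "mood_predictions"
    ))
  }

  dict <- feature_dictionary(imputed$panels[[1]])
  # working panels: imputed sensors, observed moods
  working <- purrr::map(imputed$panels, function(p) {
    p$sad <- imputed$observed$sad
    p$lonely <- imputed$observed$lonely
    add_outcome(p)
  })

  run_one_hour <- function(k, t) {
    win <- build_window(working[[k]], t, lookback)
    if (win$skip) {
      return(list(
        records = empty_records(),
        ledger = tibble::tibble(
          imputation_id = k, hour_index = as.integer(t), person_id = persons,
          status = "skipped_empty_window", mtry = NA_integer_,
          splitrule = NA_character_, n_train = NA_integer_
        )
      ))
    }
    nomo_seed <- derive_seed(seed, k, t, 0L)
    oof <- oof_nomothetic(win, dict, nomothetic, nomo_seed)
    nomo_fit <- fit_nomothetic(win, dict, nomothetic, nomo_seed)
    stacked <- win
    stacked$training <- augment_features(win$training, oof)
    targets <- if (fit_persons == "all") {
      persons
    } else {
      obs_t <- dplyr::filter(observed_mood, .data$hour_index == t, !is.na(.data$mood))
      intersect(persons, obs_t$person_id)
    }
    fits <- list()
    ledger_rows <- purrr::map(targets, function(p) {
      ids <- derive_seed(seed, k, t, match(p, persons))
      fit <- fit_idiographic(stacked$training, p, dict, weights, idiographic, ids)
      fits[[p]] <<- fit
      tibble::tibble(
        imputation_id = k, hour_index = as.integer(t), person_id = p,
        status = "fitted", mtry = as.integer(fit$best$mtry),
        splitrule = fit$best$splitrule, n_train = nrow(stacked$training)
      )
    })
    recs <- predict_hour(nomo_fit, fits, stacked, k, observed_mood)
    ledger <- if (length(ledger_rows)) {
      purrr::list_rbind(ledger_rows)
    } else {
      tibble::tibble(
        imputation_id = integer(), hour_index = integer(),
        person_id = character(), status = character(), mtry = integer(),
        splitrule = character(), n_train = integer()
      )
    }
    list(records = recs, ledger = ledger)
  }

  tasks <- tidyr::expand_grid(k = seq_len(imputed$m), t = as.integer(hours))
  runner <- function(i) run_one_hour(tasks$k[i], tasks$t[i])
  results <- if (jobs > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(tasks)), runner, mc.cores = jobs)
  } else {
    lapply(seq_len(nrow(tasks)), runner)
  }
  structure(
    list(
      records = purrr::list_rbind(purrr::map(results, "records")),
      ledger = purrr::list_rbind(purrr::map(results, "ledger")),
      m = imputed$m, hours = as.integer(hours), dry_run = FALSE
    ),
    class = "mood_predictions"
  )
}

#' @export
print.mood_predictions <- function(x, ...) {
  cat(sprintf(
    "<mood_predictions> %d records, ledger of %d fits (%s)\n",
    nrow(x$records), nrow(x$ledger),
    if (x$dry_run) "dry run" else sprintf("m = %d", x$m)
  ))
  invisible(x)
}
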