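#' Full-run configuration
#'
#' Bundles everything a complete simulate-impute-fit-evaluate run needs. The
#' master seed drives every source of randomness; sub-seeds are derived from
#' it per consumer, so a run is idempotent given an identical config.
#' Round-trips losslessly through YAML via [write_run_config()] /
#' [read_run_config()].
#'
#' @param cohort A [cohort_config()].
#' @param m Number of imputed copies.
#' @param lookback Rolling-window length (hours).
#' @param weights A [weight_scheme()].
#' @param nomothetic A [nomothetic_config()].
#' @param idiographic An [idiographic_config()].
#' @param hours Optional explicit target hours.
#' @param fit_persons Passed to [run_pipeline()].
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), m = 5L, lookback = 24L,
                       weights = weight_scheme(),
                       nomothetic = nomothetic_config(),
                       idiographic = idiographic_config(),
                       hours = NULL, fit_persons = "all", seed = 1L) {
  structure(
    list(
      cohort = cohort, m = as.integer(m), lookback = as.integer(lookback),
      weights = weights, nomothetic = nomothetic, idiographic = idiographic,
      hours = if (is.null(hours)) NULL else as.integer(hours),
      fit_persons = fit_persons, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  flat <- lapply(config, function(x) if (is.list(x)) unclass(x) else x)
  flat$cohort$race_distribution <- as.list(flat$cohort$race_distribution)
  yaml::write_yaml(flat, path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  needed <- c("cohort", "m", "lookback", "weights", "nomothetic", "idiographic", "seed")
  missing_keys <- setdiff(needed, names(raw))
  if (length(missing_keys)) {
    rlang::abort(
      paste0("config is missing key(s): ", paste(missing_keys, collapse = ", ")),
      class = "moodcast_config_error"
    )
  }
  cohort <- raw$cohort
  # renormalise: YAML prints floats at finite precision
  rd <- unlist(cohort$race_distribution)
  cohort$race_distribution <- rd / sum(rd)
  run_config(
    cohort = do.call(cohort_config, cohort),
    m = raw$m, lookback = raw$lookback,
    weights = do.call(weight_scheme, raw$weights),
    nomothetic = do.call(nomothetic_config, raw$nomothetic),
    idiographic = do.call(idiographic_config, raw$idiographic),
    hours = raw$hours,
    fit_persons = if (is.null(raw$fit_persons)) "all" else raw$fit_persons,
    seed = raw$seed
  )
}

# write outputs atomically: everything lands in a quarantine directory that
# is renamed into place only on success, so partial runs are never reused
with_quarantine <- function(out_dir, body) {
  tmp <- paste0(out_dir, ".partial")
  if (dir.exists(tmp)) unlink(tmp, recursive = TRUE)
  dir.create(tmp, recursive = TRUE)
  files <- body(tmp)
  manifest <- list(
    created = format(Sys.time(), tz = "UTC"),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("moodcast")),
    files = lapply(files, function(f) {
      list(name = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  file.rename(tmp, out_dir)
  invisible(out_dir)
}

#' Simulate a cohort and write its panel files
#'
#' Writes `panel.csv`, `profiles.csv`, `truth.csv` and a `manifest.json`
#' (content hashes of every output) to `out_dir`. Outputs are quarantined in
#' a `.partial` directory until the run completes.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
mood_simulate <- function(config, out_dir) {
  cohort <- generate_cohort(config$cohort)
  with_quarantine(out_dir, function(tmp) {
    files <- c(
      write_panel(cohort$panel, file.path(tmp, "panel.csv")),
      write_profiles(cohort$profiles, file.path(tmp, "profiles.csv"))
    )
    readr::write_csv(cohort$truth, file.path(tmp, "truth.csv"), progress = FALSE)
    write_run_config(config, file.path(tmp, "config.yaml"))
    c(files, file.path(tmp, c("truth.csv", "config.yaml")))
  })
}

#' Fit the pipeline on a simulated (or supplied) panel directory
#'
#' Imputes the panel `m` times, runs the two-phase rolling-window pipeline,
#' and writes `predictions.csv` and `ledger.csv` (plus a manifest).
#'
#' @param config A [run_config()].
#' @param panel_dir Directory holding `panel.csv` (from [mood_simulate()]).
#' @param out_dir Output directory.
#' @param dry_run Emit the planned-fit ledger without fitting.
#' @param jobs Worker processes over target hours.
#' @return The [run_pipeline()] result, invisibly.
#' @export
mood_run <- function(config, panel_dir, out_dir, dry_run = FALSE, jobs = 1L) {
  panel <- read_panel(file.path(panel_dir, "panel.csv"))
  imputed <- impute_panel(panel, m = config$m, seed = derive_seed(config$seed, 7L))
  preds <- run_pipeline(
    imputed,
    hours = config$hours, lookback = config$lookback,
    weights = config$weights, nomothetic = config$nomothetic,
    idiographic = config$idiographic, seed = config$seed,
    fit_persons = config$fit_persons, dry_run = dry_run, jobs = jobs
  )
  with_quarantine(out_dir, function(tmp) {
    readr::write_csv(preds$records, file.path(tmp, "predictions.csv"), progress = FALSE)
    readr::write_csv(preds$ledger, file.path(tmp, "ledger.csv"), progress = FALSE)
    file.path(tmp, c("predictions.csv", "ledger.csv"))
  })
  invisible(preds)
}

#' Evaluate predictions and write the report files
#'
#' Writes the pooled correlation, per-person table, Fisher average and the
#' two sensitivity analyses as delimited text, plus a forest plot and
#' trajectory plot (PDF).
#'
#' @param predictions A [run_pipeline()] result or a `predictions.csv` path.
#' @param profiles Profile tibble or `profiles.csv` path.
#' @param out_dir Output directory.
#' @param imputed Optional [impute_panel()] result for imputation-averaged
#'   lagged outcomes.
#' @return The `mood_evaluation`, invisibly.
#' @export
mood_evaluate <- function(predictions, profiles, out_dir, imputed = NULL) {
  if (is.character(predictions)) {
    predictions <- readr::read_csv(predictions,
      col_types = readr::cols(person_id = readr::col_character()),
      progress = FALSE
    )
  }
  if (is.character(profiles)) profiles <- read_profiles(profiles)
  ev <- evaluate_predictions(predictions)
  pairs <- add_lagged_outcome(ev$pairs, imputed)
  mod <- race_moderation_test(pairs, profiles)
  lag <- tryCatch(
    lagged_outcome_test(pairs),
    moodcast_insufficient_data = function(e) NULL
  )
  with_quarantine(out_dir, function(tmp) {
    readr::write_csv(glance(ev), file.path(tmp, "pooled.csv"), progress = FALSE)
    readr::write_csv(ev$per_person, file.path(tmp, "per_person.csv"), progress = FALSE)
    readr::write_csv(glance(mod), file.path(tmp, "race_moderation.csv"), progress = FALSE)
    if (!is.null(lag)) {
      readr::write_csv(glance(lag), file.path(tmp, "lagged_control.csv"), progress = FALSE)
    }
    summaries <- file.path(tmp, "model_summaries.txt")
    sink(summaries)
    print(ev)
    print(mod)
    if (!is.null(mod$model)) print(summary(mod$model))
    if (!is.null(lag)) {
      print(lag)
      print(summary(lag$model))
    }
    sink()
    ggplot2::ggsave(file.path(tmp, "forest_plot.pdf"), autoplot(ev),
      width = 6, height = 8
    )
    ggplot2::ggsave(
      file.path(tmp, "trajectories.pdf"),
      plot_trajectories(ev$pairs),
      width = 10, height = 8
    )
    setdiff(list.files(tmp, full.names = TRUE), file.path(tmp, "manifest.json"))
  })
  invisible(ev)
}

#' Run the full pipeline end to end
#'
#' simulate -> impute -> fit -> evaluate -> report, writing `simulate/`,
#' `run/` and `evaluate/` subdirectories of `out_dir`. Idempotent given an
#' identical config (including seed).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @param dry_run Ledger-only execution.
#' @param jobs Worker processes.
#' @return List with the cohort, predictions and evaluation, invisibly.
#' @export
mood_all <- function(config, out_dir, dry_run = FALSE, jobs = 1L) {
  sim_dir <- file.path(out_dir, "simulate")
  run_dir <- file.path(out_dir, "run")
  eval_dir <- file.path(out_dir, "evaluate")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mood_simulate(config, sim_dir)
  preds <- mood_run(config, sim_dir, run_dir, dry_run = dry_run, jobs = jobs)
  ev <- NULL
  if (!dry_run && nrow(preds$records) > 0) {
    panel <- read_panel(file.path(sim_dir, "panel.csv"))
    imputed <- impute_panel(panel, m = config$m, seed = derive_seed(config$seed, 7L))
    ev <- mood_evaluate(
      preds, file.path(sim_dir, "profiles.csv"), eval_dir,
      imputed = imputed
    )
  }
  invisible(list(predictions = preds, evaluation = ev))
}
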