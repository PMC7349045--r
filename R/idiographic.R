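#' Configuration of the person-weighted (idiographic) forest stage
#'
#' The second modelling phase fits, for each person, a randomized-forest
#' regression on the stacked window (sensor features plus the nomothetic
#' prediction) with the person's rows up-weighted. Hyperparameters are chosen
#' by grid search over three per-split candidate counts (evenly spaced
#' integers between 1 and the number of predictors) crossed with two split
#' rules (`variance` and `extratrees`), evaluated strictly inside the training
#' window: by out-of-bag error (`tune_method = "oob"`, the forest's built-in
#' internal cross-validation; the default) or by `cv_folds`-fold
#' person-blocked cross-validation (`tune_method = "cv"`). Ties break toward
#' the smaller candidate count, then the `variance` rule.
#'
#' @param forest_size Trees in the final forest.
#' @param split_rules Candidate split rules.
#' @param grid_length Number of per-split candidate values (3).
#' @param cv_folds Folds for the `"cv"` tuning path.
#' @param tune_method `"oob"` or `"cv"`.
#' @param tune_trees Trees used during tuning fits (default
#'   `max(50, forest_size %/% 2)`; out-of-bag rankings stabilise well before
#'   the full ensemble size).
#' @return A list of class `idiographic_config`.
#' @export
idiographic_config <- function(forest_size = 300L,
                               split_rules = c("variance", "extratrees"),
                               grid_length = 3L,
                               cv_folds = 3L,
                               tune_method = c("oob", "cv"),
                               tune_trees = NULL) {
  tune_method <- match.arg(tune_method)
  if (is.null(tune_trees)) tune_trees <- max(50L, forest_size %/% 2L)
  if (grid_length != 3L) {
    rlang::abort("the per-split candidate grid has exactly 3 values.",
      class = "moodcast_config_error"
    )
  }
  structure(
    list(
      forest_size = as.integer(forest_size),
      split_rules = match.arg(split_rules, c("variance", "extratrees"),
        several.ok = TRUE
      ),
      grid_length = 3L, cv_folds = as.integer(cv_folds),
      tune_method = tune_method, tune_trees = as.integer(tune_trees)
    ),
    class = "idiographic_config"
  )
}

# three evenly spaced integer per-split candidate counts in [1, p], sorted
mtry_grid <- function(p, length_out = 3L) {
  sort(unique(pmin(p, pmax(1L, round(seq(1, p, length.out = length_out))))))
}

#' Fit one person's idiographically weighted forest
#'
#' @param stacked_training Training rows carrying the features and a
#'   `yhat_nomothetic` column (see [augment_features()]).
#' @param person_id The focal person.
#' @param dict A [feature_dictionary()].
#' @param weights A [weight_scheme()].
#' @param config An [idiographic_config()].
#' @param seed Integer seed; tuning fits and the final fit derive child seeds
#'   from it.
#' @return An object of class `idiographic_fit` with the fitted `ranger`
#'   forest, the chosen hyperparameters and the tuning table.
#' @export
fit_idiographic <- function(stacked_training, person_id, dict,
                            weights = weight_scheme(),
                            config = idiographic_config(), seed = 1L) {
  stopifnot(inherits(weights, "weight_scheme"), inherits(config, "idiographic_config"))
  if (!"yhat_nomothetic" %in% names(stacked_training)) {
    rlang::abort("training rows lack the stacked `yhat_nomothetic` feature.",
      class = "moodcast_alignment_error"
    )
  }
  w <- ifelse(stacked_training$person_id == person_id,
    weights$target_weight, weights$other_weight
  )
  keep <- w > 0
  rows <- stacked_training[keep, , drop = FALSE]
  w <- w[keep]
  if (nrow(rows) < 2L) {
    rlang::abort("fewer than 2 positively weighted training rows.",
      class = "moodcast_insufficient_data"
    )
  }
  X <- cbind(feature_matrix(rows, dict), yhat_nomothetic = rows$yhat_nomothetic)
  y <- rows$mood
  p <- ncol(X)
  grid <- tidyr::expand_grid(
    splitrule = factor(config$split_rules, levels = c("variance", "extratrees")),
    mtry = mtry_grid(p, config$grid_length)
  ) |>
    dplyr::mutate(splitrule = as.character(.data$splitrule)) |>
    dplyr::arrange(.data$mtry, .data$splitrule)

  # constant weights are no weighting at all; passing NULL keeps the exact
  # degeneracy to the unweighted pooled forest under a shared seed
  cw <- if (length(unique(w)) == 1L) NULL else w

  score_one <- function(mtry, splitrule, gseed) {
    if (config$tune_method == "oob") {
      fit <- ranger::ranger(
        x = X, y = y, num.trees = config$tune_trees, mtry = mtry,
        splitrule = splitrule, case.weights = cw, num.threads = 1,
        seed = gseed, verbose = FALSE
      )
      fit$prediction.error
    } else {
      persons <- unique(rows$person_id)
      set.seed(gseed)
      fold_of <- sample(rep_len(seq_len(config$cv_folds), length(persons)))
      names(fold_of) <- persons
      folds <- fold_of[rows$person_id]
      errs <- purrr::map_dbl(sort(unique(folds)), function(f) {
        hold <- folds == f
        if (all(hold) || !any(hold)) {
          return(NA_real_)
        }
        fit <- ranger::ranger(
          x = X[!hold, , drop = FALSE], y = y[!hold],
          num.trees = config$tune_trees, mtry = mtry, splitrule = splitrule,
          case.weights = if (is.null(cw)) NULL else w[!hold],
          num.threads = 1, seed = gseed, verbose = FALSE
        )
        pred <- stats::predict(fit, data = X[hold, , drop = FALSE],
          num.threads = 1
        )$predictions
        sum(w[hold] * (y[hold] - pred)^2) / sum(w[hold])
      })
      mean(errs, na.rm = TRUE)
    }
  }
  scores <- purrr::pmap_dbl(
    list(grid$mtry, grid$splitrule, seq_len(nrow(grid))),
    function(m, s, i) score_one(m, s, derive_seed(seed, 21L, i))
  )
  best <- grid[which.min(scores), ]
  forest <- ranger::ranger(
    x = X, y = y, num.trees = config$forest_size, mtry = best$mtry,
    splitrule = best$splitrule, case.weights = cw, num.threads = 1,
    seed = derive_seed(seed, 99L), verbose = FALSE
  )
  structure(
    list(
      forest = forest, person_id = person_id, dict = dict,
      best = as.list(best), tuning = dplyr::mutate(grid, score = scores),
      weights = weights, config = config, p_stacked = p
    ),
    class = "idiographic_fit"
  )
}

#' @describeIn fit_idiographic Predict raw-scale mood for stacked rows.
#' @param object An `idiographic_fit`.
#' @param rows Stacked panel rows (must carry `yhat_nomothetic`).
#' @param ... Unused.
#' @export
predict.idiographic_fit <- function(object, rows, ...) {
  X <- cbind(
    feature_matrix(rows, object$dict),
    yhat_nomothetic = rows$yhat_nomothetic
  )
  as.numeric(stats::predict(object$forest, data = X, num.threads = 1)$predictions)
}
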