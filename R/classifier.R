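# Gradient-boosted slide classifier over the four aggregation
# features. Selection by stratified fivefold cross-validation over a
# small hyperparameter grid, final fit on all slides, thresholded
# prediction at a configurable operating point (default 0.7, chosen to
# favour sensitivity in a screening setting).

#' Classifier configuration
#'
#' @param n_folds Number of stratified cross-validation folds.
#' @param grid Data frame of hyperparameter candidates with columns
#'   `trees`, `depth`, `learning_rate`, `min_leaf`. The default is a
#'   compact grid suited to a 4-feature input space.
#' @param decision_threshold Probability cut-off above which (`>=`) a
#'   slide is called high risk.
#' @param seed Integer seed driving fold assignment and fitting.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(n_folds = 5L,
                              grid = default_hyperparameter_grid(),
                              decision_threshold = 0.7,
                              seed = 1L) {
  if (n_folds < 2) {
    rlang::abort("`n_folds` must be >= 2", class = "wsitriage_config_error")
  }
  needed <- c("trees", "depth", "learning_rate", "min_leaf")
  if (!is.data.frame(grid) || nrow(grid) == 0 ||
      !all(needed %in% names(grid))) {
    rlang::abort(
      "`grid` must be a non-empty data frame with columns trees, depth, learning_rate, min_leaf",
      class = "wsitriage_config_error"
    )
  }
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    rlang::abort("`decision_threshold` must lie in (0, 1)",
                 class = "wsitriage_config_error")
  }
  structure(list(n_folds = as.integer(n_folds), grid = tibble::as_tibble(grid),
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

#' @rdname classifier_config
#' @export
default_hyperparameter_grid <- function() {
  tidyr::expand_grid(trees = c(50L, 200L), depth = c(2L, 3L),
                     learning_rate = c(0.1, 0.3), min_leaf = c(1L, 5L))
}

feature_columns <- function(data) {
  setdiff(names(data)[vapply(data, is.numeric, logical(1))],
          c("slide_id", "label"))
}

classifier_matrix <- function(data, feature_names) {
  missing <- setdiff(feature_names, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing feature columns: ",
                        paste(missing, collapse = ", ")),
                 class = "wsitriage_input_error")
  }
  m <- as.matrix(data[, feature_names, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) {
    rlang::abort("features must be finite", class = "wsitriage_input_error")
  }
  m
}

check_labels <- function(label) {
  bad <- setdiff(unique(label), risk_levels())
  if (length(bad) > 0) {
    rlang::abort("labels must be 'low_risk' or 'high_risk'",
                 class = "wsitriage_input_error")
  }
  if (length(unique(label)) < 2) {
    rlang::abort("both classes must be present",
                 class = "wsitriage_input_error")
  }
  as.integer(label == "high_risk")
}

# Stratified fold assignment: within each class a seeded permutation is
# dealt round-robin over folds, so fold class balance is as even as
# arithmetic allows.
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < n_folds) {
        rlang::abort("each class needs at least `n_folds` slides",
                     class = "wsitriage_input_error")
      }
      fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds),
                                                    length(idx))
    }
  })
  fold
}

xgb_params <- function(hp, seed) {
  list(objective = "binary:logistic", max_depth = as.integer(hp$depth),
       eta = hp$learning_rate, min_child_weight = hp$min_leaf,
       nthread = 1L, seed = as.integer(seed))
}

fit_booster <- function(x, y, hp, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(params = xgb_params(hp, seed), data = dtrain,
                     nrounds = as.integer(hp$trees), verbose = 0)
}

predict_booster <- function(booster, x) {
  as.numeric(stats::predict(booster,
                            xgboost::xgb.DMatrix(x, nthread = 1)))
}

#' Cross-validated hyperparameter selection
#'
#' Runs seeded stratified k-fold cross-validation of a gradient-boosted
#' tree classifier for every grid point and selects the one with the
#' highest mean held-out accuracy (probability cut 0.5 for the
#' selection accuracy). Ties are broken in favour of fewer trees, then
#' lower depth, then lower learning rate, then smaller minimum leaf
#' size.
#'
#' @param data Tibble with `slide_id`, `label`
#'   (`"high_risk"`/`"low_risk"`) and numeric feature columns.
#' @param config A [classifier_config()].
#' @return A `triage_cv` object: list with `best` (one-row tibble of
#'   chosen hyperparameters), `cv` (full grid results with
#'   `mean_accuracy` and per-fold accuracies), `n_folds`, `seed`.
#' @export
cross_validate_select <- function(data, config = classifier_config()) {
  y <- check_labels(data$label)
  feats <- feature_columns(data)
  x <- classifier_matrix(data, feats)
  fold <- stratified_folds(y, config$n_folds, config$seed)
  grid <- config$grid
  fold_acc <- matrix(NA_real_, nrow = nrow(grid), ncol = config$n_folds)
  for (g in seq_len(nrow(grid))) {
    hp <- grid[g, ]
    for (k in seq_len(config$n_folds)) {
      tr <- fold != k
      booster <- fit_booster(x[tr, , drop = FALSE], y[tr], hp,
                             seed = config$seed + k)
      p <- predict_booster(booster, x[!tr, , drop = FALSE])
      fold_acc[g, k] <- mean((p >= 0.5) == (y[!tr] == 1))
    }
  }
  cv <- dplyr::mutate(grid, mean_accuracy = rowMeans(fold_acc),
                      fold_accuracy = purrr::map(seq_len(nrow(grid)),
                                                 function(g) fold_acc[g, ]))
  ranked <- dplyr::arrange(cv, dplyr::desc(.data$mean_accuracy),
                           .data$trees, .data$depth, .data$learning_rate,
                           .data$min_leaf)
  structure(
    list(best = ranked[1, c("trees", "depth", "learning_rate", "min_leaf",
                            "mean_accuracy")],
         cv = cv, n_folds = config$n_folds, seed = config$seed,
         feature_names = feats),
    class = "triage_cv"
  )
}

#' @export
print.triage_cv <- function(x, ...) {
  cat(sprintf(
    "<triage_cv> %d-fold CV over %d grid points; best mean accuracy %.3f\n",
    x$n_folds, nrow(x$cv), x$best$mean_accuracy))
  print(x$best)
  invisible(x)
}

#' Fit the final slide classifier
#'
#' Refits the boosted-tree ensemble on every slide with the selected
#' hyperparameters, as the deployed model.
#'
#' @param data As in [cross_validate_select()].
#' @param hyperparameters One-row data frame (`trees`, `depth`,
#'   `learning_rate`, `min_leaf`), e.g. the `best` element of a
#'   `triage_cv`.
#' @param seed Integer seed.
#' @param cv Optional `triage_cv` report to carry along.
#' @return A `slide_classifier` object.
#' @export
fit_final <- function(data, hyperparameters, seed = 1L, cv = NULL) {
  y <- check_labels(data$label)
  feats <- if (!is.null(cv)) cv$feature_names else feature_columns(data)
  x <- classifier_matrix(data, feats)
  booster <- fit_booster(x, y, hyperparameters, seed)
  p <- predict_booster(booster, x)
  structure(
    list(booster = booster,
         booster_json = rawToChar(xgboost::xgb.save.raw(booster,
                                                        raw_format = "json")),
         hyperparameters = tibble::as_tibble(hyperparameters)[
           , c("trees", "depth", "learning_rate", "min_leaf")],
         feature_names = feats,
         n_train = nrow(data),
         train_accuracy = mean((p >= 0.5) == (y == 1)),
         seed = as.integer(seed),
         cv = cv),
    class = "slide_classifier"
  )
}

#' @export
print.slide_classifier <- function(x, ...) {
  hp <- x$hyperparameters
  cat(sprintf(
    "<slide_classifier> %d trees, depth %d, lr %.2f, min leaf %g; trained on %d slides (accuracy %.3f)\n",
    hp$trees, hp$depth, hp$learning_rate, hp$min_leaf, x$n_train,
    x$train_accuracy))
  invisible(x)
}

#' Train a slide classifier end to end
#'
#' Convenience wrapper: [cross_validate_select()] then [fit_final()].
#'
#' @inheritParams cross_validate_select
#' @return A `slide_classifier`.
#' @export
train_slide_classifier <- function(data, config = classifier_config()) {
  cv <- cross_validate_select(data, config)
  fit_final(data, cv$best, seed = config$seed, cv = cv)
}

#' Predict slide risk
#'
#' Scores slides with the fitted ensemble and thresholds the
#' probability of high risk: a slide is called high risk when its
#' probability is greater than or equal to the threshold, so lowering
#' the threshold can only add slides to the high-risk set.
#'
#' @param clf A `slide_classifier`.
#' @param data Tibble with the classifier's feature columns (and
#'   optionally `slide_id`).
#' @param threshold Probability cut-off in (0, 1); default 0.7.
#' @return Tibble: `slide_id` (if present), `probability_high`,
#'   `prediction`.
#' @export
predict_risk <- function(clf, data, threshold = 0.7) {
  x <- classifier_matrix(data, clf$feature_names)
  p <- predict_booster(clf$booster, x)
  out <- tibble::tibble(
    probability_high = p,
    prediction = ifelse(p >= threshold, "high_risk", "low_risk")
  )
  if ("slide_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(slide_id = data$slide_id), out)
  }
  out
}

#' Persist / restore a slide classifier as JSON
#'
#' The ensemble is stored in xgboost's portable JSON format inside a
#' versioned wrapper document, so predictions are reproducible across
#' platforms.
#'
#' @param clf A `slide_classifier`.
#' @param path JSON file path.
#' @return `read_classifier()` returns a `slide_classifier`.
#' @export
write_classifier <- function(clf, path) {
  doc <- list(
    format = "wsitriage_slide_classifier",
    format_version = 1L,
    hyperparameters = as.list(clf$hyperparameters),
    feature_names = clf$feature_names,
    n_train = clf$n_train,
    train_accuracy = clf$train_accuracy,
    seed = clf$seed,
    booster_json = clf$booster_json
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "wsitriage_slide_classifier")) {
    rlang::abort("not a wsitriage classifier file",
                 class = "wsitriage_io_error")
  }
  booster <- xgboost::xgb.load.raw(charToRaw(doc$booster_json))
  structure(
    list(booster = booster,
         booster_json = doc$booster_json,
         hyperparameters = tibble::as_tibble(doc$hyperparameters),
         feature_names = doc$feature_names,
         n_train = doc$n_train,
         train_accuracy = doc$train_accuracy,
         seed = doc$seed,
         cv = NULL),
    class = "slide_classifier"
  )
}
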