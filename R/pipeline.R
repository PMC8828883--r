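# End-to-end orchestration: simulate disjoint train and validation
# cohorts, segment with the oracle backend, aggregate features, select
# and fit the classifier on the training cohort only, predict and
# evaluate on the validation cohort, and persist every intermediate so
# each stage is re-runnable from disk.

#' Pipeline configuration
#'
#' One global seed deterministically derives every stage seed (see
#' `derive_seed`), so stages can be re-run in isolation. The default
#' cohort shape mirrors a resection-trained, biopsy-validated screen:
#' 105 resection-like training slides and 150 biopsy-like validation
#' slides (biopsies are smaller: a 2 x 2 tile frame instead of 3 x 3).
#'
#' @param seed Global integer seed.
#' @param train,validation Lists of [synthetic_config()] overrides for
#'   the two cohorts (e.g. `list(n_slides = 20)`).
#' @param features [feature_config()] overrides.
#' @param classifier [classifier_config()] overrides (the
#'   hyperparameter grid itself is not configurable from YAML).
#' @param decision_threshold Operating probability cut-off.
#' @param render_images If `TRUE`, rasterize slide PNGs and run the
#'   tissue-mask and tiling stages, writing mask PNGs and tile
#'   manifests. The slide-triage path itself is geometric and does not
#'   need pixel data.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            train = list(),
                            validation = list(),
                            features = list(),
                            classifier = list(),
                            decision_threshold = 0.7,
                            render_images = FALSE) {
  cfg <- list(seed = as.integer(seed), train = train,
              validation = validation, features = features,
              classifier = classifier,
              decision_threshold = decision_threshold,
              render_images = isTRUE(render_images))
  validate_pipeline_config(cfg)
}

pipeline_schema <- list(
  top = c("seed", "train", "validation", "features", "classifier",
          "decision_threshold", "render_images"),
  required = c("seed", "decision_threshold"),
  cohort = c("n_slides", "high_risk_prevalence", "image_width",
             "image_height", "mpp", "count_mean_high", "count_mean_low",
             "category_weights_high", "category_weights_low",
             "area_meanlog", "area_sdlog", "certainty_correct",
             "certainty_false", "spurious_rate"),
  features = c("certainty_threshold", "flag_certainty", "flag_area_mm2",
               "percentile", "high_risk_categories",
               "filter_mean_percentile"),
  classifier = c("n_folds")
)

#' Validate a pipeline configuration
#'
#' Schema-checks a config (a list, or a YAML file path): unknown keys
#' are rejected, required keys must be present, and ranges are
#' enforced with field-level error messages. Parsing, serializing with
#' [write_pipeline_config()] and re-parsing is the identity.
#'
#' @param config A config list or a YAML file path.
#' @return The validated `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  s <- pipeline_schema
  unknown <- setdiff(names(config), s$top)
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config keys: ",
                        paste(unknown, collapse = ", ")),
                 class = "wsitriage_config_error")
  }
  missing <- setdiff(s$required, names(config))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing required config keys: ",
                        paste(missing, collapse = ", ")),
                 class = "wsitriage_config_error")
  }
  for (cohort in c("train", "validation")) {
    extra <- setdiff(names(config[[cohort]]), s$cohort)
    if (length(extra) > 0) {
      rlang::abort(paste0("unknown keys in `", cohort, "`: ",
                          paste(extra, collapse = ", ")),
                   class = "wsitriage_config_error")
    }
  }
  extra <- setdiff(names(config$features), s$features)
  if (length(extra) > 0) {
    rlang::abort(paste0("unknown keys in `features`: ",
                        paste(extra, collapse = ", ")),
                 class = "wsitriage_config_error")
  }
  extra <- setdiff(names(config$classifier), s$classifier)
  if (length(extra) > 0) {
    rlang::abort(paste0("unknown keys in `classifier`: ",
                        paste(extra, collapse = ", ")),
                 class = "wsitriage_config_error")
  }
  if (!is.numeric(config$decision_threshold) ||
      config$decision_threshold <= 0 || config$decision_threshold >= 1) {
    rlang::abort("`decision_threshold` must lie in (0, 1)",
                 class = "wsitriage_config_error")
  }
  if (!is.numeric(config$seed)) {
    rlang::abort("`seed` must be an integer",
                 class = "wsitriage_config_error")
  }
  # materialize stage configs now so field errors surface here
  invisible(resolve_cohort_config(config, "train", 0L))
  invisible(resolve_cohort_config(config, "validation", 0L))
  invisible(do.call(feature_config, config$features %||% list()))
  config$render_images <- isTRUE(config$render_images)
  structure(config, class = "pipeline_config")
}

#' @rdname validate_pipeline_config
#' @param path YAML output path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

cohort_defaults <- function(role) {
  if (role == "train") {
    list(n_slides = 105L)
  } else {
    # biopsy-like: smaller frame (2 x 2 tiles)
    list(n_slides = 150L, image_width = 1550L, image_height = 1044L)
  }
}

resolve_cohort_config <- function(config, role, seed) {
  args <- utils::modifyList(cohort_defaults(role),
                            config[[role]] %||% list())
  args$seed <- seed
  do.call(synthetic_config, args)
}

#' Run the full pipeline
#'
#' Generates disjoint train and validation cohorts, computes features
#' from oracle segmentation output, selects hyperparameters by
#' cross-validation and fits the classifier on the training cohort
#' only, predicts and evaluates on the validation cohort, and writes
#' all artifacts under `out_dir`: cohort manifests and GeoJSONs,
#' `features_train.csv`, `features_validation.csv`, `cv_report.csv`,
#' `model.json`, `predictions.csv`, `report.json`,
#' `run_metadata.json` and the resolved `config.yaml`. Deterministic:
#' the same config produces byte-identical reports.
#'
#' @param config A `pipeline_config` (or YAML path).
#' @param out_dir Run directory (created).
#' @param verbose Log each stage.
#' @return Invisibly, a list with the fitted classifier, predictions,
#'   and the `triage_eval` report.
#' @export
run_all <- function(config = pipeline_config(), out_dir, verbose = TRUE) {
  config <- validate_pipeline_config(config)
  log_stage <- function(...) if (verbose) message("[wsitriage] ", ...)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    rlang::abort(paste0("cannot create run directory: ", out_dir),
                 class = "wsitriage_io_error")
  }

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ",
                          conditionMessage(e)),
                   class = "wsitriage_stage_error", parent = e)
    })
  }

  cohorts <- list()
  for (role in c("train", "validation")) {
    log_stage("simulate: ", role, " cohort")
    cohort_cfg <- resolve_cohort_config(config, role,
                                        derive_seed(config$seed,
                                                    paste0("simulate_", role)))
    dir <- file.path(out_dir, role)
    ds <- run_stage(paste0("simulate_", role), function() {
      generate_dataset(cohort_cfg, out_dir = dir,
                       render = config$render_images)
    })
    # cohort-distinct slide ids guard against train/validation leakage
    ds$manifest$slide_id <- paste0(role, "_", ds$manifest$slide_id)
    for (i in seq_along(ds$slides)) {
      sid <- ds$manifest$slide_id[i]
      ds$slides[[i]]$slide_id <- sid
      ds$slides[[i]]$seg$slide_id <- sid
    }
    cohorts[[role]] <- ds
  }

  if (config$render_images) {
    log_stage("mask/tile: tissue masks and tile manifests")
    run_stage("mask_tile", function() {
      for (role in c("train", "validation")) {
        tiles <- purrr::map_dfr(cohorts[[role]]$slides, function(s) {
          mask <- compute_tissue_mask(s$image)
          tile_slide(s$image, mask)
        })
        write_tile_manifest(tiles, file.path(out_dir, role, "tiles.csv"))
      }
    })
  }

  log_stage("features: aggregating segmentation output")
  fcfg <- do.call(feature_config, config$features %||% list())
  feats <- list()
  for (role in c("train", "validation")) {
    ft <- run_stage("features", function() {
      features_table(purrr::map(cohorts[[role]]$slides, "seg"), fcfg)
    })
    ft <- dplyr::left_join(
      ft, cohorts[[role]]$manifest[, c("slide_id", "true_label")],
      by = "slide_id"
    )
    names(ft)[names(ft) == "true_label"] <- "label"
    utils::write.csv(ft, file.path(out_dir,
                                   paste0("features_", role, ".csv")),
                     row.names = FALSE)
    feats[[role]] <- ft
  }

  log_stage("train: cross-validated selection and final fit")
  ccfg_args <- config$classifier %||% list()
  ccfg_args$seed <- derive_seed(config$seed, "train")
  ccfg_args$decision_threshold <- config$decision_threshold
  ccfg <- do.call(classifier_config, ccfg_args)
  clf <- run_stage("train", function() {
    train_slide_classifier(feats$train, ccfg)
  })
  utils::write.csv(
    dplyr::select(clf$cv$cv, -"fold_accuracy"),
    file.path(out_dir, "cv_report.csv"), row.names = FALSE
  )
  write_classifier(clf, file.path(out_dir, "model.json"))

  log_stage("predict: validation cohort at threshold ",
            config$decision_threshold)
  preds <- run_stage("predict", function() {
    predict_risk(clf, feats$validation, threshold = config$decision_threshold)
  })
  utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)

  log_stage("evaluate: confusion metrics and ROC")
  eval_data <- dplyr::left_join(
    preds, feats$validation[, c("slide_id", "label")], by = "slide_id"
  )
  names(eval_data)[names(eval_data) == "label"] <- "truth"
  report <- run_stage("evaluate", function() {
    evaluate_predictions(eval_data)
  })
  write_evaluation_report(report, file.path(out_dir, "report.json"))

  write_pipeline_config(config, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(
    list(
      package = "wsitriage",
      package_version = as.character(utils::packageVersion("wsitriage")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      config_hash = rlang::hash(unclass(config))
    ),
    file.path(out_dir, "run_metadata.json"), auto_unbox = TRUE
  )
  log_stage("done: ", out_dir)
  invisible(list(classifier = clf, predictions = preds, report = report,
                 features = feats))
}
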