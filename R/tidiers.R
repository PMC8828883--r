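# broom-style tidiers for fitted objects and evaluation reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation report
#'
#' @param x A `triage_cv` from [cross_validate_select()].
#' @param ... Unused.
#' @return Tibble: one row per grid point with `mean_accuracy`.
#' @export
tidy.triage_cv <- function(x, ...) {
  dplyr::select(x$cv, -"fold_accuracy")
}

#' @rdname tidy.triage_cv
#' @export
glance.triage_cv <- function(x, ...) {
  dplyr::bind_cols(x$best,
                   tibble::tibble(n_folds = x$n_folds,
                                  n_grid = nrow(x$cv), seed = x$seed))
}

#' Tidy a fitted slide classifier
#'
#' `tidy()` reports per-feature gain importances; `glance()` the chosen
#' hyperparameters and training summary.
#'
#' @param x A `slide_classifier`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.slide_classifier <- function(x, ...) {
  imp <- tryCatch(
    xgboost::xgb.importance(model = x$booster),
    error = function(e) NULL
  )
  if (is.null(imp) || nrow(imp) == 0) {
    return(tibble::tibble(feature = x$feature_names, gain = NA_real_))
  }
  tibble::tibble(feature = imp$Feature, gain = imp$Gain,
                 cover = imp$Cover, frequency = imp$Frequency)
}

#' @rdname tidy.slide_classifier
#' @export
glance.slide_classifier <- function(x, ...) {
  dplyr::bind_cols(
    x$hyperparameters,
    tibble::tibble(n_train = x$n_train, train_accuracy = x$train_accuracy,
                   cv_accuracy = if (!is.null(x$cv))
                     x$cv$best$mean_accuracy else NA_real_)
  )
}

#' Tidy an evaluation report
#'
#' `tidy()` returns the metrics in long form; `glance()` a one-row
#' summary.
#'
#' @param x A `triage_eval` from [evaluate_predictions()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.triage_eval <- function(x, ...) {
  m <- glance(x)
  tidyr::pivot_longer(m, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.triage_eval
#' @export
glance.triage_eval <- function(x, ...) {
  dplyr::bind_cols(x$metrics, tibble::tibble(auc = x$auc))
}

#' ROC curve plot
#'
#' @param object A `triage_eval` with scores (so the ROC sweep
#'   exists).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.triage_eval <- function(object, ...) {
  if (is.null(object$roc)) {
    rlang::abort("no ROC available: evaluate with `probability_high` scores",
                 class = "wsitriage_input_error")
  }
  ggplot2::ggplot(object$roc,
                  ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Feature separation plot
#'
#' Scatter of the two continuous headline features colored by label —
#' a quick visual check of cohort separability.
#'
#' @param features Tibble with `f_area_pct`, `f_wmean` and `label`.
#' @return A ggplot.
#' @export
plot_feature_separation <- function(features) {
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$f_area_pct, y = .data$f_wmean,
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_sqrt() +
    ggplot2::labs(x = "High-risk area (% of tissue, sqrt scale)",
                  y = "Area-weighted mean certainty", colour = NULL) +
    ggplot2::theme_minimal()
}
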