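# Confusion-matrix metrics and ROC/AUC. High risk is the positive
# class everywhere (screening framing: sensitivity is the rate at
# which truly high-risk slides are flagged).

#' Confusion counts
#'
#' @param truth,prediction Character vectors of `"high_risk"` /
#'   `"low_risk"`, aligned element-wise (join on slide_id upstream).
#' @return Named integer vector `c(tp, tn, fp, fn)`.
#' @export
confusion_counts <- function(truth, prediction) {
  if (length(truth) != length(prediction)) {
    rlang::abort("`truth` and `prediction` must have equal length",
                 class = "wsitriage_input_error")
  }
  bad <- setdiff(unique(c(truth, prediction)), risk_levels())
  if (length(bad) > 0) {
    rlang::abort("labels must be 'low_risk' or 'high_risk'",
                 class = "wsitriage_input_error")
  }
  t_pos <- truth == "high_risk"
  p_pos <- prediction == "high_risk"
  c(tp = sum(t_pos & p_pos), tn = sum(!t_pos & !p_pos),
    fp = sum(!t_pos & p_pos), fn = sum(t_pos & !p_pos))
}

#' Metrics from confusion counts
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/N`, F1 `2TP/(2TP+FP+FN)`. A rate whose denominator is zero
#' is reported as `NA` (missing), never coerced to 0.
#'
#' @param counts Named vector from [confusion_counts()].
#' @return One-row tibble of counts and rates.
#' @export
triage_metrics <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  n <- tp + tn + fp + fn
  if (n == 0) {
    rlang::abort("all counts are zero", class = "wsitriage_input_error")
  }
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn, n = n,
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    accuracy = (tp + tn) / n,
    f1 = rate(2 * tp, 2 * tp + fp + fn)
  )
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold (prediction positive when
#' `score >= threshold`) and computes the ROC polygon; the AUC is its
#' trapezoid area, which equals the pairwise concordance statistic
#' (ties counted 1/2).
#'
#' @param truth Character vector of `"high_risk"` / `"low_risk"`; both
#'   classes must be present.
#' @param score Numeric scores (probability of high risk).
#' @return List with `roc` (tibble: `threshold`, `sensitivity`,
#'   `fpr` = 1 - specificity) and `auc`.
#' @export
roc_auc <- function(truth, score) {
  if (length(truth) != length(score)) {
    rlang::abort("`truth` and `score` must have equal length",
                 class = "wsitriage_input_error")
  }
  y <- truth == "high_risk"
  if (!any(y) || all(y)) {
    rlang::abort("both classes must be present to compute a ROC curve",
                 class = "wsitriage_input_error")
  }
  thresholds <- c(Inf, sort(unique(score), decreasing = TRUE))
  np <- sum(y); nn <- sum(!y)
  tpr <- vapply(thresholds, function(t) sum(score >= t & y) / np, numeric(1))
  fpr <- vapply(thresholds, function(t) sum(score >= t & !y) / nn, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(
    roc = tibble::tibble(threshold = thresholds, sensitivity = tpr,
                         fpr = fpr),
    auc = auc
  )
}

#' Evaluate slide predictions against ground truth
#'
#' @param data Tibble with columns `truth` and `prediction` (risk
#'   labels), optionally `probability_high` (enables ROC/AUC) and
#'   `slide_id`.
#' @return A `triage_eval` object: confusion counts, rates, and (when
#'   scores are available) AUC and the ROC sweep table. Use [tidy()] /
#'   [glance()] / [ggplot2::autoplot()] on it.
#' @export
evaluate_predictions <- function(data) {
  if (!all(c("truth", "prediction") %in% names(data))) {
    rlang::abort("`data` needs `truth` and `prediction` columns",
                 class = "wsitriage_input_error")
  }
  counts <- confusion_counts(data$truth, data$prediction)
  metrics <- triage_metrics(counts)
  out <- list(counts = counts, metrics = metrics, auc = NA_real_,
              roc = NULL, n = nrow(data))
  if ("probability_high" %in% names(data) &&
      length(unique(data$truth)) == 2) {
    r <- roc_auc(data$truth, data$probability_high)
    out$auc <- r$auc
    out$roc <- r$roc
  }
  structure(out, class = "triage_eval")
}

#' @export
print.triage_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<triage_eval> n=%d  TP=%d TN=%d FP=%d FN=%d\n  sensitivity %.3f  specificity %.3f  accuracy %.3f  F1 %.3f  AUC %s\n",
    m$n, m$tp, m$tn, m$fp, m$fn, m$sensitivity, m$specificity, m$accuracy,
    m$f1, ifelse(is.na(x$auc), "-", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param eval A `triage_eval`.
#' @param path Output path.
#' @export
write_evaluation_report <- function(eval, path) {
  doc <- list(
    counts = as.list(eval$counts),
    metrics = as.list(eval$metrics[, c("sensitivity", "specificity",
                                       "accuracy", "f1")]),
    auc = eval$auc,
    n = eval$n
  )
  if (!is.null(eval$roc)) {
    roc <- eval$roc
    roc$threshold[!is.finite(roc$threshold)] <- "Inf"
    doc$roc <- roc
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 10,
                       na = "null")
  invisible(path)
}
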