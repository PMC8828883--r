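#' Histological annotation categories
#'
#' The seven categories used to annotate colorectal slides, and the
#' subset regarded as high risk (signs of dysplasia or malignancy).
#' The remaining five cover benign and inflammatory findings.
#'
#' @return `wsi_categories()` returns a character vector of the 7 category
#'   names; `high_risk_categories()` returns the high-risk subset.
#' @export
#' @examples
#' wsi_categories()
#' high_risk_categories()
wsi_categories <- function() {
  c(
    "benign_gland",
    "adenoca_or_hgd",
    "low_grade_dysplasia",
    "blood_vessel",
    "necrosis",
    "mucin",
    "inflammation"
  )
}

#' @rdname wsi_categories
#' @export
high_risk_categories <- function() {
  c("adenoca_or_hgd", "low_grade_dysplasia")
}

#' Risk labels
#'
#' Binary slide / tile triage labels.
#'
#' @return Character vector `c("low_risk", "high_risk")`.
#' @export
risk_levels <- function() c("low_risk", "high_risk")

#' Rendering colors for synthetic slides
#'
#' Fixed RGB colors (rows, in \[0,1\]) used when rasterizing each
#' category onto a synthetic slide. Arbitrary constants: they only give
#' the tissue mask and tiling realistic colored structure, loosely
#' echoing the conventional overlay palette (green benign, orange
#' dysplastic, red malignant, pink vessels, yellow inflammation).
#'
#' @return A 7x3 numeric matrix with category row names.
#' @export
category_colors <- function() {
  m <- rbind(
    benign_gland        = c(0.55, 0.75, 0.55),
    adenoca_or_hgd      = c(0.75, 0.30, 0.30),
    low_grade_dysplasia = c(0.90, 0.55, 0.25),
    blood_vessel        = c(0.90, 0.60, 0.75),
    necrosis            = c(0.55, 0.45, 0.40),
    mucin               = c(0.70, 0.80, 0.90),
    inflammation        = c(0.85, 0.80, 0.35)
  )
  colnames(m) <- c("r", "g", "b")
  m
}

validate_category <- function(category, arg = "category") {
  bad <- setdiff(unique(category), wsi_categories())
  if (length(bad) > 0) {
    rlang::abort(
      paste0("`", arg, "` contains unknown categories: ",
             paste(bad, collapse = ", ")),
      class = "wsitriage_input_error"
    )
  }
  invisible(category)
}
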