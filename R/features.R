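# Slide-level risk features aggregated from segmentation output, and
# the tile-labeling rule.

#' Feature configuration
#'
#' Thresholds for the four slide-level features. Defaults follow the
#' screening protocol: only objects with certainty strictly greater
#' than 70% count towards the high-risk area percentage; the Boolean
#' flag fires when objects above 85% certainty cover a cumulative area
#' of at least 0.1 mm^2; the percentile feature is the area-weighted
#' bottom 1-percentile of certainties.
#'
#' @param certainty_threshold Certainty cut (strict `>`) for the area
#'   feature.
#' @param flag_certainty Certainty cut (strict `>`) for the flag
#'   feature.
#' @param flag_area_mm2 Cumulative area (mm^2, `>=`) required to set
#'   the flag.
#' @param percentile Percentile (of 100) for the weighted-percentile
#'   feature.
#' @param high_risk_categories Categories counted as high risk.
#' @param filter_mean_percentile If `TRUE`, restrict the weighted-mean
#'   and weighted-percentile features to objects above
#'   `certainty_threshold` as well (default `FALSE`: the certainty
#'   filter applies only to the area feature).
#' @return A `feature_config` list.
#' @export
feature_config <- function(certainty_threshold = 0.70,
                           flag_certainty = 0.85,
                           flag_area_mm2 = 0.1,
                           percentile = 1,
                           high_risk_categories = NULL,
                           filter_mean_percentile = FALSE) {
  if (certainty_threshold <= 0 || certainty_threshold >= 1 ||
      flag_certainty <= 0 || flag_certainty >= 1) {
    rlang::abort("certainty thresholds must lie in (0, 1)",
                 class = "wsitriage_config_error")
  }
  if (flag_area_mm2 <= 0) {
    rlang::abort("`flag_area_mm2` must be > 0",
                 class = "wsitriage_config_error")
  }
  if (percentile <= 0 || percentile >= 100) {
    rlang::abort("`percentile` must lie in (0, 100)",
                 class = "wsitriage_config_error")
  }
  if (is.null(high_risk_categories)) {
    high_risk_categories <- wsitriage::high_risk_categories()
  }
  validate_category(high_risk_categories, "high_risk_categories")
  structure(
    list(certainty_threshold = certainty_threshold,
         flag_certainty = flag_certainty,
         flag_area_mm2 = flag_area_mm2,
         percentile = percentile,
         high_risk_categories = high_risk_categories,
         filter_mean_percentile = filter_mean_percentile),
    class = "feature_config"
  )
}

#' Label a tile from overlapping geometries
#'
#' A tile is high risk if any geometry of a high-risk category
#' intersects its half-open extent `[x0, x0+width) x [y0, y0+height)`
#' with positive area — "any amount" of overlap suffices. The same rule
#' applies whether the geometries are ground-truth annotations or model
#' output.
#'
#' @param tile One-row tibble (or list) with `x0`, `y0`, `width`,
#'   `height`.
#' @param geometries Tibble with `category` and `polygon` columns
#'   (annotation regions or segmented objects).
#' @param high_risk High-risk category subset.
#' @return `"high_risk"` or `"low_risk"`.
#' @export
label_tile <- function(tile, geometries,
                       high_risk = high_risk_categories()) {
  hr <- geometries[geometries$category %in% high_risk, , drop = FALSE]
  if (nrow(hr) == 0) return("low_risk")
  x0 <- tile$x0; y0 <- tile$y0
  x1 <- x0 + tile$width; y1 <- y0 + tile$height
  overlaps <- purrr::map_lgl(hr$polygon, function(p) {
    polygon_rect_intersection_area(p, x0, y0, x1, y1) > 1e-9
  })
  if (any(overlaps)) "high_risk" else "low_risk"
}

#' Label every tile of a slide
#'
#' @param tiles Tile tibble from [tile_slide()].
#' @param geometries As in [label_tile()].
#' @param high_risk High-risk category subset.
#' @return `tiles` with a `label` column appended.
#' @export
label_tiles <- function(tiles, geometries,
                        high_risk = high_risk_categories()) {
  tiles$label <- purrr::map_chr(seq_len(nrow(tiles)), function(i) {
    label_tile(tiles[i, ], geometries, high_risk)
  })
  tiles
}

#' Area-weighted percentile
#'
#' Left-continuous inverse CDF without interpolation: values are sorted
#' ascending and the smallest value whose cumulative normalized weight
#' reaches `p / 100` is returned.
#'
#' @param values Numeric vector (non-empty).
#' @param weights Positive weights, same length.
#' @param p Percentile in (0, 100\].
#' @return The weighted percentile value.
#' @export
weighted_percentile <- function(values, weights, p) {
  if (length(values) == 0) {
    rlang::abort("`values` must be non-empty",
                 class = "wsitriage_domain_error")
  }
  if (length(weights) != length(values) || any(weights <= 0)) {
    rlang::abort("`weights` must be positive and match `values` in length",
                 class = "wsitriage_input_error")
  }
  ord <- order(values)
  cw <- cumsum(weights[ord]) / sum(weights)
  values[ord][which(cw >= p / 100 - 1e-12)[1]]
}

#' Compute the four slide-level features
#'
#' Let H be the segmented objects of a high-risk category. The features
#' are:
#' \describe{
#'   \item{f_area_pct}{total area of objects in H with certainty
#'     strictly above the certainty threshold, as a percentage of the
#'     slide's tissue area;}
#'   \item{f_wmean}{area-weighted mean certainty over H;}
#'   \item{f_flag}{1 if objects in H with certainty strictly above the
#'     flag threshold cover a cumulative area of at least
#'     `flag_area_mm2`, else 0;}
#'   \item{f_wpctl1}{area-weighted bottom percentile (default 1st) of
#'     certainties over H.}
#' }
#' All four are 0 when H is empty.
#'
#' @param seg A [slide_segmentation()].
#' @param config A [feature_config()].
#' @return One-row tibble: `slide_id`, `f_area_pct`, `f_wmean`,
#'   `f_flag`, `f_wpctl1`.
#' @export
compute_slide_features <- function(seg, config = feature_config()) {
  objs <- seg$objects
  h <- objs[objs$category %in% config$high_risk_categories, , drop = FALSE]
  if (nrow(h) == 0) {
    return(tibble::tibble(slide_id = seg$slide_id, f_area_pct = 0,
                          f_wmean = 0, f_flag = 0L, f_wpctl1 = 0))
  }
  if (is.na(seg$tissue_area_mm2) || seg$tissue_area_mm2 <= 0) {
    rlang::abort("tissue area must be positive to compute features",
                 class = "wsitriage_domain_error")
  }
  conf <- h[h$certainty > config$certainty_threshold, , drop = FALSE]
  f_area_pct <- 100 * sum(conf$area_mm2) / seg$tissue_area_mm2
  hw <- if (config$filter_mean_percentile) conf else h
  if (nrow(hw) == 0) {
    f_wmean <- 0
    f_wpctl1 <- 0
  } else {
    f_wmean <- sum(hw$certainty * hw$area_mm2) / sum(hw$area_mm2)
    f_wpctl1 <- weighted_percentile(hw$certainty, hw$area_mm2,
                                    config$percentile)
  }
  flagged <- h[h$certainty > config$flag_certainty, , drop = FALSE]
  f_flag <- as.integer(sum(flagged$area_mm2) >= config$flag_area_mm2)
  tibble::tibble(slide_id = seg$slide_id, f_area_pct = f_area_pct,
                 f_wmean = f_wmean, f_flag = f_flag, f_wpctl1 = f_wpctl1)
}

#' Feature table for a set of slides
#'
#' @param segmentations List of [slide_segmentation()] objects.
#' @param config A [feature_config()].
#' @return Tibble with one row per slide, ordered by `slide_id`.
#' @export
features_table <- function(segmentations, config = feature_config()) {
  if (length(segmentations) == 0) {
    return(tibble::tibble(slide_id = character(), f_area_pct = numeric(),
                          f_wmean = numeric(), f_flag = integer(),
                          f_wpctl1 = numeric()))
  }
  out <- purrr::map_dfr(segmentations, compute_slide_features,
                        config = config)
  if (anyDuplicated(out$slide_id)) {
    rlang::abort("duplicate slide_id in segmentations",
                 class = "wsitriage_input_error")
  }
  dplyr::arrange(out, .data$slide_id)
}
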