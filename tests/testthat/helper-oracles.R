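# Independent oracles used to cross-check the package's closed-form /
# sweep implementations, plus small fixture factories.

# AUC as the pairwise concordance statistic (ties count 1/2).
concordance_auc <- function(truth, score) {
  pos <- score[truth == "high_risk"]
  neg <- score[truth == "low_risk"]
  mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
}

# Weighted percentile by replicate expansion: each value is replicated
# in proportion to its normalized weight (cumulative rounding, so the
# totals are exact), and the percentile is read off the sorted
# replicates.
replicate_percentile <- function(values, weights, p, reps = 1e6) {
  ord <- order(values)
  v <- values[ord]
  cum <- cumsum(weights[ord]) / sum(weights)
  counts <- diff(c(0, round(cum * reps)))
  x <- rep(v, counts)
  x[max(1, ceiling(p / 100 * length(x)))]
}

# Brute-force pixel rasterization of a polygon (even-odd rule on pixel
# centers); returns the covered area in px^2.
rasterize_polygon_area <- function(poly) {
  x0 <- floor(min(poly[, 1])); x1 <- ceiling(max(poly[, 1]))
  y0 <- floor(min(poly[, 2])); y1 <- ceiling(max(poly[, 2]))
  xs <- rep(seq(x0 + 0.5, x1 - 0.5), times = y1 - y0)
  ys <- rep(seq(y0 + 0.5, y1 - 0.5), each = x1 - x0)
  inside <- rep(FALSE, length(xs))
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 2]; yj <- poly[j, 2]
    xi <- poly[i, 1]; xj <- poly[j, 1]
    crosses <- ((yi > ys) != (yj > ys)) &
      (xs < (xj - xi) * (ys - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  sum(inside)
}

# Rasterization oracle for the high-risk area feature: per-object
# pixel-counted areas (the feature is a sum over objects, not a
# union), converted through mpp.
rasterized_area_pct <- function(seg, config = feature_config()) {
  objs <- seg$objects
  h <- objs[objs$category %in% config$high_risk_categories &
              objs$certainty > config$certainty_threshold, , drop = FALSE]
  if (nrow(h) == 0) return(0)
  area_px <- sum(vapply(h$polygon, rasterize_polygon_area, numeric(1)))
  100 * px_to_mm2(area_px, seg$mpp_x, seg$mpp_y) / seg$tissue_area_mm2
}

# Small synthetic configs used across tests; tiny frames keep the
# geometry light while leaving room for the default object sizes.
small_config <- function(n_slides = 10, seed = 1, ...) {
  synthetic_config(n_slides = n_slides, seed = seed,
                   image_width = 1550L, image_height = 1044L, ...)
}

# Feature table with labels for a generated cohort.
labeled_features <- function(config, feature_cfg = feature_config()) {
  ds <- generate_dataset(config)
  ft <- features_table(purrr::map(ds$slides, "seg"), feature_cfg)
  ft$label <- ds$manifest$true_label[match(ft$slide_id,
                                           ds$manifest$slide_id)]
  ft
}

# Constant mid-gray raster.
gray_raster <- function(h = 20, w = 30, value = 0.5) {
  array(value, dim = c(h, w, 3))
}

# H&E-plausible raster: synthesized from non-negative stain
# concentrations through the forward model, so stain-space operations
# (which clip negative concentrations) act on their valid domain.
plausible_he_raster <- function(h = 15, w = 15, seed = 6) {
  sm <- stain_model()
  conc <- withr::with_seed(seed, {
    array(c(runif(h * w, 0.05, 0.6), runif(h * w, 0.05, 0.6),
            rep(0, h * w)), dim = c(h, w, 3))
  })
  he_to_rgb(conc, sm)
}
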