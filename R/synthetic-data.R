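# Synthetic slide generator: seeded slides with a tissue-colored blob
# on a near-white background, gland-like elliptical regions rendered in
# per-category colors, per-category ground-truth annotations, and
# oracle segmentation output whose certainty laws are conditioned on
# the slide's true risk label. Everything downstream of scanning is
# thereby testable at desk scale with controllable separability.

#' Synthetic cohort configuration
#'
#' Defaults describe the study conditions used throughout the test
#' suite: 2325 x 1566 px slides (a 3 x 3 grid of 775 x 522 tiles) at
#' 4.0 microns per pixel (so 0.1 mm^2 = 6250 px), a 50% high-risk
#' prevalence, Poisson object counts, log-normal object areas on the
#' mm^2 scale, and Beta certainty laws — Beta(16, 2) (mean ~0.89) for
#' correctly detected objects and Beta(2, 8) (mean 0.2) for spurious
#' high-risk detections — yielding clear but imperfect separability.
#'
#' @param n_slides Number of slides in the cohort.
#' @param high_risk_prevalence Probability a slide is truly high risk.
#' @param image_width,image_height Slide size in pixels.
#' @param mpp Microns per pixel (square pixels).
#' @param count_mean_high,count_mean_low Poisson means for the number
#'   of annotated objects per slide, by true label.
#' @param category_weights_high,category_weights_low Mixture weights
#'   over the 7 categories ([wsi_categories()] order) for object
#'   categories, by true label. Low-risk slides must put zero weight on
#'   high-risk categories.
#' @param area_meanlog,area_sdlog Log-normal law for object areas,
#'   mm^2 scale.
#' @param certainty_correct,certainty_false `c(alpha, beta)` Beta laws
#'   for the oracle's certainty on correct detections and on
#'   false/spurious detections.
#' @param spurious_rate Expected spurious high-risk detections per
#'   slide (Poisson mean); these are what make low-risk slides
#'   imperfectly separable.
#' @param seed RNG seed for the cohort.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_slides = 10L,
                             high_risk_prevalence = 0.5,
                             image_width = 2325L,
                             image_height = 1566L,
                             mpp = 4.0,
                             count_mean_high = 12,
                             count_mean_low = 10,
                             category_weights_high =
                               c(0.25, 0.25, 0.15, 0.1, 0.05, 0.1, 0.1),
                             category_weights_low =
                               c(0.45, 0, 0, 0.2, 0.05, 0.1, 0.2),
                             area_meanlog = log(0.05),
                             area_sdlog = 0.5,
                             certainty_correct = c(16, 2),
                             certainty_false = c(2, 8),
                             spurious_rate = 2,
                             seed = 1L) {
  check_pos <- function(x, nm) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      rlang::abort(paste0("`", nm, "` must be strictly positive"),
                   class = "wsitriage_config_error")
    }
  }
  if (!is.numeric(n_slides) || n_slides < 0) {
    rlang::abort("`n_slides` must be >= 0", class = "wsitriage_config_error")
  }
  if (!is.numeric(high_risk_prevalence) || high_risk_prevalence < 0 ||
      high_risk_prevalence > 1) {
    rlang::abort("`high_risk_prevalence` must lie in [0, 1]",
                 class = "wsitriage_config_error")
  }
  check_pos(image_width, "image_width"); check_pos(image_height, "image_height")
  check_pos(mpp, "mpp")
  check_pos(count_mean_high, "count_mean_high")
  check_pos(count_mean_low, "count_mean_low")
  check_weights <- function(w, nm) {
    if (length(w) != 7 || any(w < 0) || sum(w) <= 0) {
      rlang::abort(paste0("`", nm, "` must be 7 non-negative weights"),
                   class = "wsitriage_config_error")
    }
    w / sum(w)
  }
  category_weights_high <- check_weights(category_weights_high,
                                         "category_weights_high")
  category_weights_low <- check_weights(category_weights_low,
                                        "category_weights_low")
  hr_idx <- match(high_risk_categories(), wsi_categories())
  if (any(category_weights_low[hr_idx] > 0)) {
    rlang::abort(
      "`category_weights_low` must put zero weight on high-risk categories",
      class = "wsitriage_config_error"
    )
  }
  check_pos(area_sdlog, "area_sdlog")
  check_pos(certainty_correct, "certainty_correct")
  check_pos(certainty_false, "certainty_false")
  if (spurious_rate < 0) {
    rlang::abort("`spurious_rate` must be >= 0",
                 class = "wsitriage_config_error")
  }
  structure(
    list(n_slides = as.integer(n_slides),
         high_risk_prevalence = high_risk_prevalence,
         image_width = as.integer(image_width),
         image_height = as.integer(image_height),
         mpp = mpp,
         count_mean_high = count_mean_high,
         count_mean_low = count_mean_low,
         category_weights_high = category_weights_high,
         category_weights_low = category_weights_low,
         area_meanlog = area_meanlog, area_sdlog = area_sdlog,
         certainty_correct = certainty_correct,
         certainty_false = certainty_false,
         spurious_rate = spurious_rate,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Corruption implied by a synthetic config: identity label flips, no
# drops, spurious high-risk detections at the configured rate.
config_corruption <- function(config) {
  oracle_corruption(
    certainty_correct = config$certainty_correct,
    certainty_incorrect = config$certainty_false,
    flip_matrix = diag(7),
    drop_rate = 0,
    spurious_rate = config$spurious_rate,
    spurious_category_weights = c(0, 0.5, 0.5, 0, 0, 0, 0),
    spurious_area_meanlog = config$area_meanlog - log(2),
    spurious_area_sdlog = config$area_sdlog
  )
}

#' Generate one synthetic slide
#'
#' Deterministic given `(config$seed, slide_index)`. The slide carries
#' a tissue blob (an ellipse filling most of the frame), non-overlapping
#' gland-like elliptical regions placed inside it by rejection sampling
#' (at most 100 attempts each), the ground-truth annotation table, the
#' true risk label (high risk iff at least one region has a high-risk
#' category), and oracle segmentation output. Rendering the RGB raster
#' is optional — the slide-level pipeline is purely geometric.
#'
#' @param config A [synthetic_config()].
#' @param slide_index 1-based index within the cohort
#'   (`<= config$n_slides`).
#' @param render If `TRUE`, rasterize the image (a [slide_image()]);
#'   otherwise `image` is `NULL`.
#' @return A `synthetic_slide`: list with `slide_id`, `image`,
#'   `regions`, `true_label`, `seg`, `tissue_ellipse`,
#'   `tissue_area_mm2`, `mpp`.
#' @export
generate_slide <- function(config, slide_index, render = FALSE) {
  if (slide_index < 1 || slide_index > config$n_slides) {
    rlang::abort("`slide_index` must lie in 1..n_slides",
                 class = "wsitriage_config_error")
  }
  slide_id <- sprintf("slide_%04d", slide_index)
  seed <- derive_seed(config$seed, paste0("slide", slide_index))
  cats <- wsi_categories()
  hr <- high_risk_categories()
  w <- config$image_width; h <- config$image_height
  blob <- list(cx = w / 2, cy = h / 2, rx = 0.42 * w, ry = 0.40 * h,
               theta = 0)
  tissue_area_mm2 <- px_to_mm2(pi * blob$rx * blob$ry, config$mpp)

  gen <- withr::with_seed(seed, {
    true_high <- stats::runif(1) < config$high_risk_prevalence
    lambda <- if (true_high) config$count_mean_high else config$count_mean_low
    wts <- if (true_high) config$category_weights_high
           else config$category_weights_low
    n_obj <- stats::rpois(1, lambda)
    if (true_high) n_obj <- max(n_obj, 1L)
    categories <- cats[sample.int(7, n_obj, replace = TRUE, prob = wts)]
    if (true_high && !any(categories %in% hr)) {
      # a truly high-risk slide must carry at least one high-risk region
      categories[1] <- hr[sample.int(2, 1)]
    }
    area_mm2 <- stats::rlnorm(n_obj, config$area_meanlog, config$area_sdlog)
    placed <- place_ellipses(n_obj, area_mm2, blob, config$mpp)
    list(true_high = true_high, categories = categories, placed = placed)
  })

  keep <- gen$placed$placed
  ell <- gen$placed$ellipses[keep, , drop = FALSE]
  categories <- gen$categories[keep]
  polys <- purrr::map(seq_len(nrow(ell)), function(i) {
    ellipse_polygon(ell[i, "cx"], ell[i, "cy"], ell[i, "rx"], ell[i, "ry"],
                    ell[i, "theta"])
  })
  regions <- annotation_regions(categories, polys, mpp_x = config$mpp)
  regions$cx <- ell[, "cx"]; regions$cy <- ell[, "cy"]
  regions$rx <- ell[, "rx"]; regions$ry <- ell[, "ry"]
  regions$theta <- ell[, "theta"]
  true_label <- if (any(regions$category %in% hr)) "high_risk" else "low_risk"

  seg <- oracle_segment(
    regions, config_corruption(config),
    mpp_x = config$mpp, tissue_area_mm2 = tissue_area_mm2,
    slide_id = slide_id, tissue_ellipse = blob,
    seed = derive_seed(seed, "oracle")
  )

  image <- if (render) {
    render_slide_image(config, blob, regions, slide_id)
  } else NULL

  structure(
    list(slide_id = slide_id, image = image, regions = regions,
         true_label = true_label, seg = seg, tissue_ellipse = blob,
         tissue_area_mm2 = tissue_area_mm2, mpp = config$mpp),
    class = "synthetic_slide"
  )
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("<synthetic_slide '%s'> %s, %d regions, %d predicted objects\n",
              x$slide_id, x$true_label, nrow(x$regions), nrow(x$seg$objects)))
  invisible(x)
}

# Non-overlapping ellipse placement inside the tissue blob by
# rejection sampling; overlap is tested conservatively on bounding
# circles. Objects that fail 100 attempts are skipped.
place_ellipses <- function(n, area_mm2, blob, mpp) {
  area_px <- area_mm2 * 1e6 / mpp^2
  ellipses <- matrix(NA_real_, nrow = n, ncol = 5,
                     dimnames = list(NULL, c("cx", "cy", "rx", "ry", "theta")))
  placed <- rep(FALSE, n)
  radii <- numeric(0); cxs <- numeric(0); cys <- numeric(0)
  for (i in seq_len(n)) {
    r <- sqrt(area_px[i] / pi)
    q <- stats::runif(1, 0.6, 1)
    rx <- r / sqrt(q); ry <- r * sqrt(q)
    theta <- stats::runif(1, 0, pi)
    rmax <- max(rx, ry)
    for (attempt in seq_len(100L)) {
      u <- sqrt(stats::runif(1)); a <- stats::runif(1, 0, 2 * pi)
      cx <- blob$cx + (blob$rx - rmax) * u * cos(a)
      cy <- blob$cy + (blob$ry - rmax) * u * sin(a)
      ok <- !any((cxs - cx)^2 + (cys - cy)^2 < (radii + rmax)^2)
      if (ok) {
        ellipses[i, ] <- c(cx, cy, rx, ry, theta)
        placed[i] <- TRUE
        radii <- c(radii, rmax); cxs <- c(cxs, cx); cys <- c(cys, cy)
        break
      }
    }
  }
  list(ellipses = ellipses, placed = placed)
}

# Rasterize background, tissue blob and category-colored glands.
render_slide_image <- function(config, blob, regions, slide_id) {
  w <- config$image_width; h <- config$image_height
  px <- array(0.96, dim = c(h, w, 3))
  cols <- category_colors()
  blob_mask <- ellipse_pixel_mask(w, h, blob$cx, blob$cy, blob$rx, blob$ry,
                                  blob$theta)
  tissue_col <- c(0.91, 0.79, 0.86)
  for (ch in 1:3) {
    m <- px[, , ch]
    m[blob_mask] <- tissue_col[ch]
    px[, , ch] <- m
  }
  for (i in seq_len(nrow(regions))) {
    bb_x <- range(regions$polygon[[i]][, 1])
    bb_y <- range(regions$polygon[[i]][, 2])
    c0 <- max(1L, floor(bb_x[1])); c1 <- min(w, ceiling(bb_x[2]))
    r0 <- max(1L, floor(bb_y[1])); r1 <- min(h, ceiling(bb_y[2]))
    if (c1 < c0 || r1 < r0) next
    sub <- ellipse_pixel_mask(c1 - c0 + 1L, r1 - r0 + 1L,
                              regions$cx[i] - (c0 - 1L),
                              regions$cy[i] - (r0 - 1L),
                              regions$rx[i], regions$ry[i], regions$theta[i])
    col <- cols[regions$category[i], ]
    for (ch in 1:3) {
      m <- px[r0:r1, c0:c1, ch]
      m[sub] <- col[ch]
      px[r0:r1, c0:c1, ch] <- m
    }
  }
  slide_image(px, mpp_x = config$mpp, slide_id = slide_id)
}

#' Generate a synthetic cohort
#'
#' Generates `config$n_slides` slides and, when `out_dir` is given,
#' writes each slide's image (PNG + mpp sidecar, if rendered),
#' annotations and segmentation (GeoJSON), and a manifest CSV with
#' columns `slide_id,true_label,image,annotations,segmentation`.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional output directory (created if needed).
#' @param render Rasterize slide images (see [generate_slide()]).
#' @return List with `slides` (list of `synthetic_slide`) and
#'   `manifest` (tibble).
#' @export
generate_dataset <- function(config, out_dir = NULL, render = FALSE) {
  slides <- purrr::map(seq_len(config$n_slides), function(i) {
    generate_slide(config, i, render = render)
  })
  manifest <- tibble::tibble(
    slide_id = purrr::map_chr(slides, "slide_id"),
    true_label = purrr::map_chr(slides, "true_label"),
    image = if (render) paste0(purrr::map_chr(slides, "slide_id"), ".png")
            else NA_character_,
    annotations = paste0(purrr::map_chr(slides, "slide_id"),
                         ".annotations.geojson"),
    segmentation = paste0(purrr::map_chr(slides, "slide_id"),
                          ".segmentation.geojson")
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) &&
        !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
      rlang::abort(paste0("cannot create output directory: ", out_dir),
                   class = "wsitriage_io_error")
    }
    for (k in seq_along(slides)) {
      s <- slides[[k]]
      if (render) write_slide_image(s$image, file.path(out_dir,
                                                       manifest$image[k]))
      write_annotations_geojson(s$regions,
                                file.path(out_dir, manifest$annotations[k]),
                                slide_id = s$slide_id,
                                mpp_x = config$mpp)
      write_segmentation_geojson(s$seg,
                                 file.path(out_dir, manifest$segmentation[k]))
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE, na = "")
  }
  list(slides = slides, manifest = manifest)
}
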