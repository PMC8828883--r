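# Segmentation backend contract and the ground-truth-corrupting oracle.
#
# A backend is anything with a `segment_slide()` method returning a
# `slide_segmentation`. The oracle backend stands in for a trained
# gland-segmentation network: it converts ground-truth annotation
# regions into predicted objects with configurable corruption (label
# flips, dropped annotations, spurious objects, Beta-distributed
# prediction certainties), so the downstream slide classifier can be
# exercised and stress-tested without any trained weights.

#' Annotation region table
#'
#' Builds the canonical tibble of polygonal annotation regions.
#'
#' @param category Character vector of categories (see
#'   [wsi_categories()]).
#' @param polygon List of n x 2 (x, y) vertex matrices, pixel
#'   coordinates.
#' @param mpp_x,mpp_y Microns per pixel, used to derive `area_mm2`.
#' @return Tibble with columns `region_id`, `category`, `polygon`
#'   (list), `area_px`, `area_mm2`.
#' @export
annotation_regions <- function(category, polygon, mpp_x, mpp_y = mpp_x) {
  validate_category(category)
  area_px <- purrr::map_dbl(polygon, polygon_area)
  if (any(area_px <= 0)) {
    rlang::abort("annotation polygons must have positive area",
                 class = "wsitriage_input_error")
  }
  tibble::tibble(
    region_id = seq_along(category),
    category = category,
    polygon = polygon,
    area_px = area_px,
    area_mm2 = px_to_mm2(area_px, mpp_x, mpp_y)
  )
}

#' Slide segmentation container
#'
#' The per-slide output of any segmentation backend: a table of
#' segmented objects (polygon, category, prediction certainty, areas)
#' plus the slide's tissue area, which downstream features use as the
#' denominator.
#'
#' @param slide_id Slide identifier.
#' @param objects Tibble with columns `category`, `certainty`,
#'   `polygon`, `area_px`, `area_mm2` (zero rows allowed).
#' @param tissue_area_mm2 Tissue area of the slide in mm^2.
#' @param mpp_x,mpp_y Microns per pixel (metadata).
#' @return A `slide_segmentation` object.
#' @export
slide_segmentation <- function(slide_id, objects, tissue_area_mm2,
                               mpp_x = NA_real_, mpp_y = mpp_x) {
  if (nrow(objects) > 0) {
    validate_category(objects$category)
    if (any(objects$certainty < 0 | objects$certainty > 1)) {
      rlang::abort("certainties must lie in [0, 1]",
                   class = "wsitriage_input_error")
    }
    if (any(objects$area_px <= 0)) {
      rlang::abort("object areas must be positive",
                   class = "wsitriage_input_error")
    }
    if (tissue_area_mm2 <= 0) {
      rlang::abort("tissue_area_mm2 must be > 0 when objects are present",
                   class = "wsitriage_input_error")
    }
  }
  structure(
    list(slide_id = slide_id, objects = objects,
         tissue_area_mm2 = tissue_area_mm2,
         mpp_x = mpp_x, mpp_y = mpp_y),
    class = "slide_segmentation"
  )
}

#' @export
print.slide_segmentation <- function(x, ...) {
  cat(sprintf("<slide_segmentation '%s'> %d objects, tissue %.3g mm^2\n",
              x$slide_id, nrow(x$objects), x$tissue_area_mm2))
  invisible(x)
}

empty_objects <- function() {
  tibble::tibble(
    object_id = integer(), category = character(), certainty = numeric(),
    polygon = list(), area_px = numeric(), area_mm2 = numeric(),
    spurious = logical()
  )
}

#' Oracle corruption configuration
#'
#' Controls how [oracle_segment()] degrades ground truth into
#' predictions. Certainty laws are Beta(alpha, beta) per (category,
#' correctness); `beta <= 0` is read as a point mass at 1 and
#' `alpha <= 0` as a point mass at 0, so degenerate (perfectly
#' confident) oracles are expressible.
#'
#' @param certainty_correct,certainty_incorrect Either a length-2
#'   `c(alpha, beta)` applied to every category, or a 7 x 2 matrix
#'   (rows in [wsi_categories()] order). "Incorrect" covers flipped
#'   labels and spurious objects.
#' @param flip_matrix 7 x 7 row-stochastic confusion matrix; entry
#'   (i, j) is the probability a true category i is reported as j.
#'   Identity by default.
#' @param drop_rate Probability an annotation yields no object.
#' @param spurious_rate Expected number of spurious (false) objects per
#'   slide (Poisson mean).
#' @param spurious_category_weights Mixture weights over the 7
#'   categories for spurious objects.
#' @param spurious_area_meanlog,spurious_area_sdlog Log-normal law for
#'   spurious object areas, mm^2 scale.
#' @return An `oracle_corruption` object.
#' @export
oracle_corruption <- function(certainty_correct = c(16, 2),
                              certainty_incorrect = c(2, 8),
                              flip_matrix = diag(7),
                              drop_rate = 0,
                              spurious_rate = 0,
                              spurious_category_weights = rep(1 / 7, 7),
                              spurious_area_meanlog = log(0.02),
                              spurious_area_sdlog = 0.5) {
  cats <- wsi_categories()
  as_cert <- function(x, nm) {
    if (is.matrix(x)) {
      if (!all(dim(x) == c(7, 2))) {
        rlang::abort(paste0("`", nm, "` matrix must be 7 x 2"),
                     class = "wsitriage_config_error")
      }
      rownames(x) <- cats
      return(x)
    }
    if (length(x) != 2) {
      rlang::abort(paste0("`", nm, "` must be c(alpha, beta) or a 7x2 matrix"),
                   class = "wsitriage_config_error")
    }
    matrix(rep(x, each = 7), nrow = 7, dimnames = list(cats, c("alpha", "beta")))
  }
  if (!is.matrix(flip_matrix) || !all(dim(flip_matrix) == c(7, 7)) ||
      any(flip_matrix < 0) || any(abs(rowSums(flip_matrix) - 1) > 1e-9)) {
    rlang::abort("`flip_matrix` must be a 7x7 row-stochastic matrix",
                 class = "wsitriage_config_error")
  }
  if (drop_rate < 0 || drop_rate > 1) {
    rlang::abort("`drop_rate` must lie in [0, 1]",
                 class = "wsitriage_config_error")
  }
  if (spurious_rate < 0) {
    rlang::abort("`spurious_rate` must be >= 0",
                 class = "wsitriage_config_error")
  }
  if (length(spurious_category_weights) != 7 ||
      any(spurious_category_weights < 0) ||
      sum(spurious_category_weights) <= 0) {
    rlang::abort("`spurious_category_weights` must be 7 non-negative weights",
                 class = "wsitriage_config_error")
  }
  structure(
    list(
      certainty_correct = as_cert(certainty_correct, "certainty_correct"),
      certainty_incorrect = as_cert(certainty_incorrect, "certainty_incorrect"),
      flip_matrix = flip_matrix,
      drop_rate = drop_rate,
      spurious_rate = spurious_rate,
      spurious_category_weights =
        spurious_category_weights / sum(spurious_category_weights),
      spurious_area_meanlog = spurious_area_meanlog,
      spurious_area_sdlog = spurious_area_sdlog
    ),
    class = "oracle_corruption"
  )
}

#' @rdname oracle_corruption
#' @export
zero_corruption <- function() {
  oracle_corruption(certainty_correct = c(1, 0),
                    certainty_incorrect = c(1, 0),
                    flip_matrix = diag(7), drop_rate = 0, spurious_rate = 0)
}

# Beta draw with degenerate limits: beta <= 0 -> 1, alpha <= 0 -> 0.
rbeta_deg <- function(n, alpha, beta) {
  if (beta <= 0) return(rep(1, n))
  if (alpha <= 0) return(rep(0, n))
  stats::rbeta(n, alpha, beta)
}

#' Oracle segmentation of ground-truth annotations
#'
#' Turns annotation regions into predicted objects under the configured
#' corruption: each annotation survives with probability
#' `1 - drop_rate`; its reported category is drawn from the flip-matrix
#' row of the true category; its certainty is drawn from the Beta law
#' for (reported category, correctness). A Poisson(`spurious_rate`)
#' number of spurious elliptical objects is placed on tissue with the
#' "incorrect" certainty law. Deterministic given `seed`.
#'
#' @param regions Annotation tibble from [annotation_regions()].
#' @param corruption An [oracle_corruption()].
#' @param mpp_x,mpp_y Microns per pixel.
#' @param tissue_area_mm2 Slide tissue area (mm^2), carried into the
#'   result.
#' @param slide_id Slide identifier.
#' @param tissue_ellipse Optional list `(cx, cy, rx, ry, theta)`
#'   describing the tissue blob; spurious objects are centered inside
#'   it. Falls back to the bounding box of `regions`.
#' @param seed Optional integer seed; `NULL` uses the current RNG
#'   state.
#' @return A [slide_segmentation()].
#' @export
oracle_segment <- function(regions, corruption, mpp_x, mpp_y = mpp_x,
                           tissue_area_mm2, slide_id = "slide",
                           tissue_ellipse = NULL, seed = NULL) {
  run <- function() {
    cats <- wsi_categories()
    objs <- empty_objects()
    if (nrow(regions) > 0) {
      kept <- stats::runif(nrow(regions)) >= corruption$drop_rate
      kept_regions <- regions[kept, , drop = FALSE]
      if (nrow(kept_regions) > 0) {
        true_idx <- match(kept_regions$category, cats)
        obs_idx <- vapply(true_idx, function(i) {
          sample.int(7, 1, prob = corruption$flip_matrix[i, ])
        }, integer(1))
        correct <- obs_idx == true_idx
        certainty <- vapply(seq_along(obs_idx), function(k) {
          law <- if (correct[k]) corruption$certainty_correct
                 else corruption$certainty_incorrect
          rbeta_deg(1, law[obs_idx[k], 1], law[obs_idx[k], 2])
        }, numeric(1))
        objs <- tibble::tibble(
          object_id = seq_along(obs_idx),
          category = cats[obs_idx],
          certainty = certainty,
          polygon = kept_regions$polygon,
          area_px = kept_regions$area_px,
          area_mm2 = kept_regions$area_mm2,
          spurious = FALSE
        )
      }
    }
    n_spur <- if (corruption$spurious_rate > 0) {
      stats::rpois(1, corruption$spurious_rate)
    } else 0L
    if (n_spur > 0) {
      spur <- make_spurious_objects(n_spur, corruption, mpp_x, mpp_y,
                                    tissue_ellipse, regions)
      spur$object_id <- nrow(objs) + seq_len(nrow(spur))
      objs <- dplyr::bind_rows(objs, spur)
    }
    slide_segmentation(slide_id, objs, tissue_area_mm2, mpp_x, mpp_y)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

make_spurious_objects <- function(n, corruption, mpp_x, mpp_y,
                                  tissue_ellipse, regions) {
  cats <- wsi_categories()
  cat_idx <- sample.int(7, n, replace = TRUE,
                        prob = corruption$spurious_category_weights)
  area_mm2 <- stats::rlnorm(n, corruption$spurious_area_meanlog,
                            corruption$spurious_area_sdlog)
  area_px <- area_mm2 * 1e6 / (mpp_x * mpp_y)
  centers <- spurious_centers(n, tissue_ellipse, regions)
  polys <- purrr::map(seq_len(n), function(i) {
    r <- sqrt(area_px[i] / pi)
    q <- stats::runif(1, 0.6, 1)
    ellipse_polygon(centers[i, 1], centers[i, 2],
                    r / sqrt(q), r * sqrt(q), stats::runif(1, 0, pi))
  })
  shoelace <- purrr::map_dbl(polys, polygon_area)
  tibble::tibble(
    object_id = seq_len(n),
    category = cats[cat_idx],
    certainty = vapply(cat_idx, function(ci) {
      rbeta_deg(1, corruption$certainty_incorrect[ci, 1],
                corruption$certainty_incorrect[ci, 2])
    }, numeric(1)),
    polygon = polys,
    area_px = shoelace,
    area_mm2 = px_to_mm2(shoelace, mpp_x, mpp_y),
    spurious = TRUE
  )
}

spurious_centers <- function(n, tissue_ellipse, regions) {
  if (!is.null(tissue_ellipse)) {
    te <- tissue_ellipse
    # uniform in the ellipse by radial inversion
    u <- sqrt(stats::runif(n))
    a <- stats::runif(n, 0, 2 * pi)
    ex <- te$rx * u * cos(a); ey <- te$ry * u * sin(a)
    th <- te$theta %||% 0
    return(cbind(te$cx + ex * cos(th) - ey * sin(th),
                 te$cy + ex * sin(th) + ey * cos(th)))
  }
  if (nrow(regions) > 0) {
    allv <- do.call(rbind, regions$polygon)
    return(cbind(stats::runif(n, min(allv[, 1]), max(allv[, 1])),
                 stats::runif(n, min(allv[, 2]), max(allv[, 2]))))
  }
  rlang::abort(
    "spurious objects need a `tissue_ellipse` or non-empty `regions`",
    class = "wsitriage_config_error"
  )
}

#' Segmentation backend contract
#'
#' `segment_slide()` is the generic every backend implements: given a
#' slide image and its tissue mask, return a [slide_segmentation()]
#' whose objects carry valid categories, certainties in \[0, 1\] and
#' polygons intersecting tissue. [oracle_backend()] wraps ground-truth
#' annotations and an [oracle_corruption()] into a conforming backend;
#' an adapter around a trained model only needs a `segment_slide()`
#' method on its own class.
#'
#' @param backend A backend object.
#' @param image A [slide_image()].
#' @param mask The matching `tissue_mask`.
#' @param ... Passed to methods.
#' @return A [slide_segmentation()].
#' @export
segment_slide <- function(backend, image, mask, ...) {
  UseMethod("segment_slide")
}

#' @rdname segment_slide
#' @param annotations Named list: slide_id -> list with elements
#'   `regions` (an [annotation_regions()] tibble) and optionally
#'   `tissue_ellipse`.
#' @param corruption An [oracle_corruption()].
#' @param seed Integer seed; per-slide seeds are derived from it so
#'   each slide is independently reproducible.
#' @export
oracle_backend <- function(annotations, corruption = oracle_corruption(),
                           seed = 1L) {
  structure(list(annotations = annotations, corruption = corruption,
                 seed = seed),
            class = "oracle_backend")
}

#' @export
segment_slide.oracle_backend <- function(backend, image, mask, ...) {
  slide_id <- attr(image, "slide_id")
  ann <- backend$annotations[[slide_id]]
  if (is.null(ann)) {
    rlang::abort(paste0("oracle backend has no annotations for slide '",
                        slide_id, "'"),
                 class = "wsitriage_backend_error")
  }
  mpp <- image_mpp(image)
  oracle_segment(
    ann$regions, backend$corruption,
    mpp_x = mpp[["mpp_x"]], mpp_y = mpp[["mpp_y"]],
    tissue_area_mm2 = tissue_area_mm2(mask),
    slide_id = slide_id,
    tissue_ellipse = ann$tissue_ellipse,
    seed = derive_seed(backend$seed, slide_id)
  )
}

# Deterministic integer seed derived from a base seed and a string tag;
# kept below 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483563)
}

#' Check backend conformance
#'
#' Validates the segmentation contract: categories are among the 7
#' labels, certainties lie in \[0, 1\], areas are positive and
#' mpp-consistent, and (when a mask is supplied) each object polygon
#' intersects tissue.
#'
#' @param seg A [slide_segmentation()].
#' @param mask Optional `tissue_mask`.
#' @return `TRUE` invisibly; aborts with a descriptive error otherwise.
#' @export
check_segmentation <- function(seg, mask = NULL) {
  objs <- seg$objects
  validate_category(objs$category)
  stopifnot(all(objs$certainty >= 0 & objs$certainty <= 1))
  if (nrow(objs) > 0) {
    stopifnot(all(objs$area_px > 0))
    if (is.finite(seg$mpp_x)) {
      expected <- px_to_mm2(objs$area_px, seg$mpp_x, seg$mpp_y)
      stopifnot(all(abs(objs$area_mm2 - expected) <=
                      1e-9 * pmax(expected, 1e-12)))
    }
    if (!is.null(mask)) {
      on_tissue <- purrr::map_lgl(objs$polygon, function(p) {
        cx <- pmin(pmax(ceiling(mean(p[, 1])), 1L), ncol(mask))
        cy <- pmin(pmax(ceiling(mean(p[, 2])), 1L), nrow(mask))
        any(mask[cy, cx])
      })
      stopifnot(all(on_tissue))
    }
  }
  invisible(TRUE)
}
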