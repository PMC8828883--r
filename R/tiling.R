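#' Heuristic tissue mask
#'
#' Flags non-background pixels of an H&E slide image. A pixel is tissue
#' when its HSV saturation exceeds an Otsu-derived threshold or its
#' value (brightness) falls below 0.92 — i.e. anything that is not
#' near-white glass. Connected components smaller than `min_object_px`
#' are removed as specks. Deterministic.
#'
#' The Otsu threshold is computed on the saturation channel and capped
#' at 0.2 so that uniformly saturated images (where the between-class
#' criterion is degenerate) are still flagged as tissue.
#'
#' @param image A [slide_image()].
#' @param min_object_px Minimum connected-component size kept, pixels.
#' @return A `tissue_mask`: logical `[height, width]` matrix with
#'   attributes `tissue_area_px` and `tissue_area_mm2`.
#' @export
compute_tissue_mask <- function(image, min_object_px = 64L) {
  px <- unclass(image)
  h <- dim(px)[1]; w <- dim(px)[2]
  rgbm <- rbind(
    as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3])
  )
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)
  s <- matrix(hsv[2, ], nrow = h, ncol = w)
  v <- matrix(hsv[3, ], nrow = h, ncol = w)
  thr <- min(EBImage::otsu(s, range = c(0, 1)), 0.2)
  mask <- s > thr | v < 0.92
  if (any(mask) && min_object_px > 1) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_px)
    mask <- matrix(lab %in% keep & lab > 0, nrow = h, ncol = w)
  }
  new_tissue_mask(mask, image)
}

new_tissue_mask <- function(mask, image) {
  mpp <- image_mpp(image)
  area_px <- sum(mask)
  structure(mask,
            tissue_area_px = area_px,
            tissue_area_mm2 = px_to_mm2(area_px, mpp[["mpp_x"]], mpp[["mpp_y"]]),
            slide_id = attr(image, "slide_id"),
            class = c("tissue_mask", "matrix"))
}

#' @rdname compute_tissue_mask
#' @param mask A `tissue_mask`.
#' @export
tissue_area_px <- function(mask) attr(mask, "tissue_area_px")

#' @rdname compute_tissue_mask
#' @export
tissue_area_mm2 <- function(mask) attr(mask, "tissue_area_mm2")

#' Write a tissue mask as a 0/255 PNG
#'
#' @param mask A `tissue_mask`.
#' @param path Output PNG path.
#' @export
write_tissue_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Divide a slide into fixed-size tiles and discard tissue-free tiles
#'
#' The grid is anchored at the image origin (top-left); partial tiles at
#' the right/bottom edges are dropped. A tile is retained when its
#' tissue fraction strictly exceeds `min_tissue_fraction`; the default 0
#' keeps tiles containing any tissue at all and discards only tiles
#' with none.
#'
#' @param image A [slide_image()].
#' @param mask A `tissue_mask` aligned with `image`.
#' @param min_tissue_fraction Retention threshold on the fraction of
#'   tile pixels flagged as tissue (strict inequality).
#' @param tile_width,tile_height Tile size in pixels. Defaults 775 x 522.
#' @return A tibble, row-major order, with columns `slide_id`, `row`,
#'   `col` (0-based grid indices), `x0`, `y0` (0-based top-left pixel;
#'   the tile covers the half-open extent `[x0, x0+width) x
#'   [y0, y0+height)`), and `tissue_fraction`.
#' @export
tile_slide <- function(image, mask, min_tissue_fraction = 0,
                       tile_width = 775L, tile_height = 522L) {
  if (nrow(mask) != image_height(image) || ncol(mask) != image_width(image)) {
    rlang::abort("mask dimensions do not match image",
                 class = "wsitriage_input_error")
  }
  n_cols <- image_width(image) %/% tile_width
  n_rows <- image_height(image) %/% tile_height
  if (n_cols < 1 || n_rows < 1) {
    return(empty_tile_table())
  }
  grid <- tidyr::expand_grid(row = seq_len(n_rows) - 1L,
                             col = seq_len(n_cols) - 1L)
  frac <- purrr::map2_dbl(grid$row, grid$col, function(r, cc) {
    rows <- (r * tile_height + 1L):((r + 1L) * tile_height)
    cols <- (cc * tile_width + 1L):((cc + 1L) * tile_width)
    mean(mask[rows, cols])
  })
  out <- tibble::tibble(
    slide_id = attr(image, "slide_id") %||% "slide",
    row = grid$row,
    col = grid$col,
    x0 = grid$col * tile_width,
    y0 = grid$row * tile_height,
    width = as.integer(tile_width),
    height = as.integer(tile_height),
    tissue_fraction = frac
  )
  dplyr::filter(out, .data$tissue_fraction > min_tissue_fraction)
}

empty_tile_table <- function() {
  tibble::tibble(
    slide_id = character(), row = integer(), col = integer(),
    x0 = integer(), y0 = integer(),
    width = integer(), height = integer(),
    tissue_fraction = numeric()
  )
}

#' Crop one tile out of a slide image
#'
#' Pixel-exact crop of the tile's half-open extent.
#'
#' @param image A [slide_image()].
#' @param tile A one-row tile tibble (or list) with `x0`, `y0`, `width`,
#'   `height`.
#' @return A numeric array `[height, width, 3]`.
#' @export
crop_tile <- function(image, tile) {
  x0 <- tile$x0; y0 <- tile$y0; w <- tile$width; h <- tile$height
  if (x0 < 0 || y0 < 0 ||
      x0 + w > image_width(image) || y0 + h > image_height(image)) {
    rlang::abort("tile extent lies outside the image",
                 class = "wsitriage_bounds_error")
  }
  unclass(image)[(y0 + 1L):(y0 + h), (x0 + 1L):(x0 + w), , drop = FALSE]
}

#' Partition items into train / selection / final sets
#'
#' Splits `n_items` into three disjoint partitions by a seeded uniform
#' permutation. Sizes follow a fixed rounding rule:
#' `n_train = floor(f_train * N)`; the remainder `R` is divided between
#' selection and final as `n_sel = ceiling(R * f_sel / (f_sel +
#' f_final))` and `n_final = R - n_sel`. With the default 90/5/5
#' fractions this is floor / ceil-half / floor-half, e.g. 73,546 items
#' split as 66,191 / 3,678 / 3,677.
#'
#' @param n_items Number of items (N >= 0).
#' @param fractions Length-3 positive numeric summing to 1:
#'   (train, selection, final).
#' @param seed Integer seed for the permutation.
#' @return A tibble with columns `item` (1..N) and `partition`
#'   (factor: train / selection / final). Partition sizes depend only on
#'   `n_items` and `fractions`; membership depends on `seed`.
#' @export
split_dataset <- function(n_items, fractions = c(0.90, 0.05, 0.05),
                          seed = 1L) {
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    rlang::abort("`fractions` must be 3 positive numbers summing to 1",
                 class = "wsitriage_config_error")
  }
  sizes <- split_sizes(n_items, fractions)
  labels <- factor(rep(c("train", "selection", "final"), times = sizes),
                   levels = c("train", "selection", "final"))
  perm <- withr::with_seed(seed, sample.int(n_items))
  out <- tibble::tibble(item = seq_len(n_items),
                        partition = labels[order(perm)])
  out
}

#' @rdname split_dataset
#' @export
split_sizes <- function(n_items, fractions = c(0.90, 0.05, 0.05)) {
  n_train <- floor(fractions[1] * n_items)
  r <- n_items - n_train
  n_sel <- ceiling(r * fractions[2] / (fractions[2] + fractions[3]))
  c(train = n_train, selection = n_sel, final = r - n_sel)
}

#' Write a tile manifest CSV
#'
#' @param tiles Tile tibble from [tile_slide()].
#' @param path Output CSV path.
#' @export
write_tile_manifest <- function(tiles, path) {
  utils::write.csv(
    tiles[, c("slide_id", "row", "col", "x0", "y0", "tissue_fraction")],
    path, row.names = FALSE
  )
  invisible(path)
}
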