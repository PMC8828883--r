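# Image augmentation suite for H&E tiles.
#
# All operations take and return numeric rasters [height, width, 3]
# with values in [0, 1]. Geometric operations are lossless pixel
# permutations; photometric operations clip back into [0, 1].

#' Augmentation configuration
#'
#' Parameter laws for the seven tile augmentations, applied jointly in
#' a fixed order: rotation (0/90/180/270 degrees, equiprobable),
#' mirroring (horizontal / vertical / none, equiprobable), contrast and
#' brightness (multiplicative factors drawn uniformly from
#' \[0.7, 1.3\]), H&E color modulation (per-channel stain-concentration
#' shifts drawn uniformly from \[-0.05, 0.05\]), additive Gaussian
#' noise (sigma 0.1 on the normalized intensity scale), and Gaussian
#' blur (radius 0.1 px, i.e. the kernel standard deviation).
#'
#' @param rotation_angles Candidate right-angle rotations (degrees),
#'   sampled equiprobably.
#' @param mirror_choices Candidate mirror axes, sampled equiprobably.
#' @param contrast_range,brightness_range Length-2 ranges for the
#'   multiplicative factors.
#' @param he_delta_range Length-2 range for the stain-concentration
#'   shifts.
#' @param noise_sigma Standard deviation of the additive noise.
#' @param blur_radius Gaussian blur standard deviation in pixels.
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(rotation_angles = c(0L, 90L, 180L, 270L),
                                mirror_choices = c("horizontal", "vertical",
                                                   "none"),
                                contrast_range = c(0.7, 1.3),
                                brightness_range = c(0.7, 1.3),
                                he_delta_range = c(-0.05, 0.05),
                                noise_sigma = 0.1,
                                blur_radius = 0.1) {
  if (!all(rotation_angles %in% c(0, 90, 180, 270)) ||
      length(rotation_angles) < 1) {
    rlang::abort("`rotation_angles` must be drawn from {0, 90, 180, 270}",
                 class = "wsitriage_config_error")
  }
  if (!all(mirror_choices %in% c("horizontal", "vertical", "none")) ||
      length(mirror_choices) < 1) {
    rlang::abort(
      "`mirror_choices` must be drawn from {horizontal, vertical, none}",
      class = "wsitriage_config_error"
    )
  }
  check_range <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2]) {
      rlang::abort(paste0("`", nm, "` must be an ordered length-2 range"),
                   class = "wsitriage_config_error")
    }
  }
  check_range(contrast_range, "contrast_range")
  check_range(brightness_range, "brightness_range")
  check_range(he_delta_range, "he_delta_range")
  if (noise_sigma < 0 || blur_radius < 0) {
    rlang::abort("`noise_sigma` and `blur_radius` must be >= 0",
                 class = "wsitriage_config_error")
  }
  structure(
    list(
      rotation_angles = rotation_angles,
      mirror_choices = mirror_choices,
      contrast_range = contrast_range,
      brightness_range = brightness_range,
      he_delta_range = he_delta_range,
      noise_sigma = noise_sigma,
      blur_radius = blur_radius
    ),
    class = "augmentation_config"
  )
}

check_raster <- function(raster) {
  if (!is.array(raster) || length(dim(raster)) != 3 || dim(raster)[3] != 3) {
    rlang::abort("raster must be a [height, width, 3] array",
                 class = "wsitriage_input_error")
  }
  raster
}

#' Rotate a raster by a right angle
#'
#' Lossless axis-aligned rotation, clockwise; dimensions swap for 90
#' and 270 degrees.
#'
#' @param raster `[h, w, 3]` array.
#' @param angle One of 0, 90, 180, 270 (degrees).
#' @return Rotated raster.
#' @export
rotate_raster <- function(raster, angle) {
  check_raster(raster)
  if (!angle %in% c(0, 90, 180, 270)) {
    rlang::abort("`angle` must be one of 0, 90, 180, 270",
                 class = "wsitriage_param_error")
  }
  if (angle == 0) return(raster)
  rot1 <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])  # 90 cw
  k <- angle / 90
  out <- raster
  for (i in seq_len(k)) {
    d <- dim(out)
    new <- array(0, dim = c(d[2], d[1], 3))
    for (ch in 1:3) new[, , ch] <- rot1(matrix(out[, , ch], d[1], d[2]))
    out <- new
  }
  out
}

#' Mirror a raster
#'
#' `"horizontal"` flips left-right (columns reversed), `"vertical"`
#' flips top-bottom (rows reversed), `"none"` is the identity. Applying
#' the same flip twice is the identity.
#'
#' @param raster `[h, w, 3]` array.
#' @param axis `"horizontal"`, `"vertical"` or `"none"`.
#' @return Mirrored raster.
#' @export
mirror_raster <- function(raster, axis) {
  check_raster(raster)
  switch(axis,
    none = raster,
    horizontal = raster[, rev(seq_len(dim(raster)[2])), , drop = FALSE],
    vertical = raster[rev(seq_len(dim(raster)[1])), , , drop = FALSE],
    rlang::abort("`axis` must be 'horizontal', 'vertical' or 'none'",
                 class = "wsitriage_param_error")
  )
}

#' Adjust contrast about the image mean
#'
#' Shifts pixel values away from (factor > 1) or towards (factor < 1)
#' the mean intensity `m` of the whole image (all pixels, all
#' channels): `p' = clip(m + factor * (p - m), 0, 1)`.
#'
#' @param raster `[h, w, 3]` array.
#' @param factor Positive multiplicative factor.
#' @return Adjusted raster.
#' @export
adjust_contrast <- function(raster, factor) {
  check_raster(raster)
  if (!is.numeric(factor) || factor <= 0) {
    rlang::abort("`factor` must be positive", class = "wsitriage_param_error")
  }
  m <- mean(raster)
  clip01(m + factor * (raster - m))
}

#' Adjust brightness
#'
#' `p' = clip(factor * p, 0, 1)`.
#'
#' @inheritParams adjust_contrast
#' @return Adjusted raster.
#' @export
adjust_brightness <- function(raster, factor) {
  check_raster(raster)
  if (!is.numeric(factor) || factor <= 0) {
    rlang::abort("`factor` must be positive", class = "wsitriage_param_error")
  }
  clip01(factor * raster)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Standard H&E stain model
#'
#' Optical-density unit vectors for hematoxylin and eosin in RGB space
#' (the Ruifrok-Johnston calibration, the de facto standard when no
#' slide-specific stain matrix is available), completed with a unit
#' residual vector orthogonal to both, and a background intensity
#' `i0 = 1` on the normalized scale.
#'
#' @param hematoxylin,eosin Length-3 OD direction vectors (normalized
#'   internally).
#' @param i0 Background (unstained) intensity.
#' @return A `stain_model` with the 3x3 basis matrix `m` (columns:
#'   hematoxylin, eosin, residual) and `i0`.
#' @export
stain_model <- function(hematoxylin = c(0.650, 0.704, 0.286),
                        eosin = c(0.072, 0.990, 0.105),
                        i0 = 1.0) {
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  e <- eosin / sqrt(sum(eosin^2))
  cross <- c(h[2] * e[3] - h[3] * e[2],
             h[3] * e[1] - h[1] * e[3],
             h[1] * e[2] - h[2] * e[1])
  nc <- sqrt(sum(cross^2))
  if (!is.finite(nc) || nc < 1e-6 || i0 <= 0) {
    rlang::abort("degenerate stain basis (collinear vectors) or i0 <= 0",
                 class = "wsitriage_config_error")
  }
  structure(list(m = cbind(h = h, e = e, r = cross / nc), i0 = i0),
            class = "stain_model")
}

#' RGB to H&E stain concentrations and back
#'
#' `rgb_to_he()` converts a raster to per-pixel optical density,
#' `OD = -log10((p + eps) / i0)` with `eps = 1e-6` guarding `log(0)`,
#' and projects it onto the stain basis; channel 1 is the hematoxylin
#' concentration, channel 2 eosin, channel 3 the orthogonal residual.
#' `he_to_rgb()` inverts the transform. The pair are mutual inverses on
#' the non-clipped domain to within 1/255.
#'
#' @param raster `[h, w, 3]` RGB array in \[0, 1\].
#' @param conc `[h, w, 3]` concentration array (H, E, residual).
#' @param stain A [stain_model()].
#' @return Concentration array / RGB array.
#' @export
rgb_to_he <- function(raster, stain = stain_model()) {
  check_raster(raster)
  d <- dim(raster)
  p <- matrix(raster, ncol = 3)
  od <- -log10((p + 1e-6) / stain$i0)
  conc <- od %*% t(solve(stain$m))
  array(conc, dim = d)
}

#' @rdname rgb_to_he
#' @export
he_to_rgb <- function(conc, stain = stain_model()) {
  check_raster(conc)
  d <- dim(conc)
  od <- matrix(conc, ncol = 3) %*% t(stain$m)
  p <- stain$i0 * 10^(-od) - 1e-6
  array(clip01(p), dim = d)
}

#' H&E color augmentation
#'
#' Shifts the per-image hematoxylin and eosin concentration channels by
#' scalar amounts `delta_h` and `delta_e` (one draw per image per
#' channel), clips negative concentrations at zero, and transforms back
#' to RGB. Simulates variability in staining intensity.
#'
#' @param raster `[h, w, 3]` RGB array.
#' @param delta_h,delta_e Concentration shifts, each in
#'   \[-0.05, 0.05\].
#' @param stain A [stain_model()].
#' @param delta_range Allowed shift range (parameter check).
#' @return Augmented RGB raster.
#' @export
he_color_augment <- function(raster, delta_h, delta_e,
                             stain = stain_model(),
                             delta_range = c(-0.05, 0.05)) {
  if (delta_h < delta_range[1] || delta_h > delta_range[2] ||
      delta_e < delta_range[1] || delta_e > delta_range[2]) {
    rlang::abort("stain deltas outside the configured range",
                 class = "wsitriage_param_error")
  }
  conc <- rgb_to_he(raster, stain)
  conc[, , 1] <- pmax(conc[, , 1] + delta_h, 0)
  conc[, , 2] <- pmax(conc[, , 2] + delta_e, 0)
  he_to_rgb(conc, stain)
}

#' Additive Gaussian noise
#'
#' Adds an independent N(0, sigma^2) draw to every pixel and channel,
#' then clips to \[0, 1\]. Deterministic given `seed`.
#'
#' @param raster `[h, w, 3]` array.
#' @param sigma Noise standard deviation (normalized intensity units).
#' @param seed Optional integer seed; `NULL` uses the current RNG
#'   state.
#' @return Noisy raster.
#' @export
add_gaussian_noise <- function(raster, sigma, seed = NULL) {
  check_raster(raster)
  if (sigma < 0) {
    rlang::abort("`sigma` must be >= 0", class = "wsitriage_param_error")
  }
  if (sigma == 0) return(raster)
  noise_fn <- function() {
    raster + array(stats::rnorm(length(raster), sd = sigma),
                   dim = dim(raster))
  }
  out <- if (is.null(seed)) noise_fn() else withr::with_seed(seed, noise_fn())
  clip01(out)
}

#' Gaussian blur
#'
#' Separable convolution with a normalized Gaussian kernel of standard
#' deviation `radius` pixels, half-sample symmetric (reflective)
#' boundaries. Total intensity is conserved to within 1e-6 relative;
#' `radius = 0` is the identity. The default 0.1 px is a near-identity
#' softening emulating slight defocus.
#'
#' @param raster `[h, w, 3]` array.
#' @param radius Kernel standard deviation in pixels.
#' @return Blurred raster.
#' @export
gaussian_blur <- function(raster, radius) {
  check_raster(raster)
  if (radius < 0) {
    rlang::abort("`radius` must be >= 0", class = "wsitriage_param_error")
  }
  if (radius == 0) return(raster)
  half <- max(1L, ceiling(3 * radius))
  k <- stats::dnorm(seq(-half, half), sd = radius)
  k <- k / sum(k)
  out <- raster
  for (ch in 1:3) {
    m <- out[, , ch]
    m <- conv_sep(m, k, half, along = "rows")
    m <- conv_sep(m, k, half, along = "cols")
    out[, , ch] <- m
  }
  out
}

# 1-D convolution of a matrix along rows or columns with reflective
# (half-sample symmetric) boundary extension: index 0 -> 1, -1 -> 2,
# n+1 -> n, n+2 -> n-1.
conv_sep <- function(m, k, half, along = c("rows", "cols")) {
  along <- match.arg(along)
  n <- if (along == "rows") nrow(m) else ncol(m)
  reflect <- function(i) {
    i[i < 1] <- 1 - i[i < 1]
    i[i > n] <- 2 * n + 1 - i[i > n]
    i
  }
  acc <- 0
  for (j in seq_along(k)) {
    off <- j - half - 1L
    idx <- reflect(seq_len(n) + off)
    shifted <- if (along == "rows") m[idx, , drop = FALSE]
               else m[, idx, drop = FALSE]
    acc <- acc + k[j] * shifted
  }
  acc
}

#' Apply the full augmentation suite to one tile
#'
#' Samples one parameter per augmentation from the configured laws and
#' applies all seven in order: rotation, mirroring, contrast,
#' brightness, H&E color modulation, Gaussian noise, Gaussian blur.
#' Rotation and mirroring may sample the identity. Deterministic given
#' `seed`.
#'
#' @param raster `[h, w, 3]` array in \[0, 1\].
#' @param config An [augmentation_config()].
#' @param seed Optional integer seed; `NULL` uses the current RNG
#'   state.
#' @param stain A [stain_model()].
#' @return Augmented raster with values in \[0, 1\].
#' @export
augment_tile <- function(raster, config = augmentation_config(),
                         seed = NULL, stain = stain_model()) {
  run <- function() {
    angle <- config$rotation_angles[sample.int(length(config$rotation_angles), 1)]
    axis <- config$mirror_choices[sample.int(length(config$mirror_choices), 1)]
    contrast <- stats::runif(1, config$contrast_range[1],
                             config$contrast_range[2])
    brightness <- stats::runif(1, config$brightness_range[1],
                               config$brightness_range[2])
    dh <- stats::runif(1, config$he_delta_range[1], config$he_delta_range[2])
    de <- stats::runif(1, config$he_delta_range[1], config$he_delta_range[2])
    out <- rotate_raster(raster, angle)
    out <- mirror_raster(out, axis)
    out <- adjust_contrast(out, contrast)
    out <- adjust_brightness(out, brightness)
    out <- he_color_augment(out, dh, de, stain,
                            delta_range = config$he_delta_range)
    out <- add_gaussian_noise(out, config$noise_sigma)
    gaussian_blur(out, config$blur_radius)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
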