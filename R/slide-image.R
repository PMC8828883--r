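#' Slide images
#'
#' A `slide_image` is an RGB raster stored as a numeric array
#' `[height, width, 3]` with channel values in \[0, 1\] (the layout
#' returned by [png::readPNG()]), carrying microns-per-pixel metadata
#' and a slide identifier as attributes. Every spatial computation in
#' the package converts pixel measurements to physical units through
#' the mpp fields.
#'
#' @param pixels Numeric array `[height, width, 3]`, values in \[0, 1\].
#' @param mpp_x,mpp_y Microns per pixel along x (columns) and y (rows);
#'   `mpp_y` defaults to `mpp_x` (square pixels).
#' @param slide_id Identifier string.
#' @return A `slide_image` object.
#' @export
slide_image <- function(pixels, mpp_x, mpp_y = mpp_x, slide_id = "slide") {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    rlang::abort("`pixels` must be a [height, width, 3] array",
                 class = "wsitriage_input_error")
  }
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1) {
    rlang::abort("image must be at least 1x1", class = "wsitriage_input_error")
  }
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1) {
    rlang::abort("channel values must lie in [0, 1]",
                 class = "wsitriage_input_error")
  }
  if (!is.numeric(mpp_x) || mpp_x <= 0 || !is.numeric(mpp_y) || mpp_y <= 0) {
    rlang::abort("`mpp_x` and `mpp_y` must be positive",
                 class = "wsitriage_config_error")
  }
  structure(pixels,
            mpp_x = mpp_x, mpp_y = mpp_y, slide_id = slide_id,
            class = c("slide_image", "array"))
}

#' @rdname slide_image
#' @param x A `slide_image`.
#' @export
image_width <- function(x) dim(x)[2]

#' @rdname slide_image
#' @export
image_height <- function(x) dim(x)[1]

#' @rdname slide_image
#' @export
image_mpp <- function(x) {
  c(mpp_x = attr(x, "mpp_x"), mpp_y = attr(x, "mpp_y"))
}

#' @export
print.slide_image <- function(x, ...) {
  mpp <- image_mpp(x)
  cat(sprintf("<slide_image '%s'> %d x %d px, mpp %.3g x %.3g\n",
              attr(x, "slide_id"), image_width(x), image_height(x),
              mpp[1], mpp[2]))
  invisible(x)
}

#' Read / write a slide image with its mpp sidecar
#'
#' Images are stored as PNG; resolution metadata travels in a JSON
#' sidecar `<image>.mpp.json` with keys `mpp_x` and `mpp_y`.
#'
#' @param path PNG file path.
#' @param image A `slide_image`.
#' @return `read_slide_image()` returns a `slide_image`;
#'   `write_slide_image()` returns `path` invisibly.
#' @export
read_slide_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] == 4) px <- px[, , 1:3, drop = FALSE]
  sidecar <- mpp_sidecar_path(path)
  if (!file.exists(sidecar)) {
    rlang::abort(paste0("missing mpp sidecar: ", sidecar),
                 class = "wsitriage_io_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  slide_image(px, mpp_x = meta$mpp_x, mpp_y = meta$mpp_y,
              slide_id = sub("\\.png$", "", basename(path)))
}

#' @rdname read_slide_image
#' @export
write_slide_image <- function(image, path) {
  png::writePNG(unclass(image)[, , , drop = FALSE], target = path)
  mpp <- image_mpp(image)
  jsonlite::write_json(
    list(mpp_x = mpp[["mpp_x"]], mpp_y = mpp[["mpp_y"]]),
    mpp_sidecar_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

mpp_sidecar_path <- function(path) paste0(sub("\\.png$", "", path), ".mpp.json")
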