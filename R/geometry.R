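# Planar geometry primitives used for annotation polygons.
#
# Coordinate convention (shared across the package): pixel units,
# origin at the image's top-left corner, x increasing rightwards
# (columns), y increasing downwards (rows). Pixel (row r, col c),
# 1-based, covers the half-open square [c-1, c) x [r-1, r); its center
# is (c - 0.5, r - 0.5). Polygons are n x 2 matrices of (x, y)
# vertices, not closed (the first vertex is not repeated).

#' Polygon area by the shoelace formula
#'
#' @param poly An n x 2 numeric matrix of (x, y) vertices (n >= 3),
#'   open ring.
#' @return Non-negative area in squared coordinate units.
#' @export
polygon_area <- function(poly) {
  if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3) {
    return(0)
  }
  x <- poly[, 1]
  y <- poly[, 2]
  xs <- c(x[-1], x[1])
  ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Vertices of an ellipse as a polygon
#'
#' @param cx,cy Center, pixel coordinates.
#' @param rx,ry Semi-axes in pixels.
#' @param theta Rotation of the rx axis, radians, clockwise in image
#'   coordinates (y down).
#' @param n Number of vertices.
#' @return An n x 2 matrix of (x, y) vertices.
#' @export
ellipse_polygon <- function(cx, cy, rx, ry, theta = 0, n = 64L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ex <- rx * cos(t)
  ey <- ry * sin(t)
  cbind(
    x = cx + ex * cos(theta) - ey * sin(theta),
    y = cy + ex * sin(theta) + ey * cos(theta)
  )
}

# Clip a polygon against the half-plane a*x + b*y <= c
# (Sutherland-Hodgman step). Returns a matrix, possibly with < 3 rows.
clip_halfplane <- function(poly, a, b, cc) {
  n <- nrow(poly)
  if (is.null(n) || n == 0) return(poly)
  d <- a * poly[, 1] + b * poly[, 2] - cc
  out_x <- numeric(0)
  out_y <- numeric(0)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    di <- d[i]; dj <- d[j]
    if (di <= 0) {
      out_x <- c(out_x, poly[i, 1]); out_y <- c(out_y, poly[i, 2])
    }
    if ((di <= 0) != (dj <= 0)) {
      t <- di / (di - dj)
      out_x <- c(out_x, poly[i, 1] + t * (poly[j, 1] - poly[i, 1]))
      out_y <- c(out_y, poly[i, 2] + t * (poly[j, 2] - poly[i, 2]))
    }
  }
  cbind(x = out_x, y = out_y)
}

#' Clip a polygon to an axis-aligned rectangle
#'
#' Sutherland-Hodgman clipping of an arbitrary simple polygon against
#' the rectangle \[x0, x1\] x \[y0, y1\].
#'
#' @param poly n x 2 matrix of (x, y) vertices.
#' @param x0,y0,x1,y1 Rectangle bounds, `x0 < x1`, `y0 < y1`.
#' @return Clipped polygon matrix (0 rows if the intersection is empty).
#' @export
clip_polygon_rect <- function(poly, x0, y0, x1, y1) {
  p <- clip_halfplane(poly, -1, 0, -x0)   # x >= x0
  p <- clip_halfplane(p, 1, 0, x1)        # x <= x1
  p <- clip_halfplane(p, 0, -1, -y0)      # y >= y0
  clip_halfplane(p, 0, 1, y1)             # y <= y1
}

#' Area of the intersection of a polygon with a rectangle
#'
#' @inheritParams clip_polygon_rect
#' @return Intersection area in squared pixel units.
#' @export
polygon_rect_intersection_area <- function(poly, x0, y0, x1, y1) {
  polygon_area(clip_polygon_rect(poly, x0, y0, x1, y1))
}

#' Convert a pixel area to mm^2
#'
#' @param area_px Area in squared pixels.
#' @param mpp_x,mpp_y Microns per pixel along x and y.
#' @return Area in mm^2 (`area_px * mpp_x * mpp_y * 1e-6`).
#' @export
px_to_mm2 <- function(area_px, mpp_x, mpp_y = mpp_x) {
  area_px * mpp_x * mpp_y * 1e-6
}

# Logical mask of pixels whose centers fall inside a rotated ellipse.
# Returns a height x width matrix; used by the renderer and by
# rasterization oracles.
ellipse_pixel_mask <- function(width, height, cx, cy, rx, ry, theta = 0) {
  xc <- seq_len(width) - 0.5
  yc <- seq_len(height) - 0.5
  dx <- matrix(xc - cx, nrow = height, ncol = width, byrow = TRUE)
  dy <- matrix(yc - cy, nrow = height, ncol = width)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / rx)^2 + (v / ry)^2 <= 1
}
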