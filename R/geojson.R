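# GeoJSON dialect for annotations and segmentations: a
# FeatureCollection of Polygon features in slide pixel coordinates,
# properties {"category": string} for ground truth plus
# {"certainty": float} for model output. Slide-level metadata
# (slide_id, mpp, tissue area) rides in a top-level "properties"
# member.

polygon_to_geojson <- function(poly) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  dimnames(ring) <- NULL
  list(type = "Polygon", coordinates = list(ring))
}

geojson_to_polygon <- function(geom) {
  ring <- geom$coordinates[[1]]
  m <- do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]])))
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) {
    m <- m[-nrow(m), , drop = FALSE]
  }
  colnames(m) <- c("x", "y")
  m
}

#' Read and write annotation GeoJSON
#'
#' @param regions An [annotation_regions()] tibble.
#' @param path File path.
#' @param slide_id Identifier stored in the file's properties.
#' @param mpp_x,mpp_y Microns per pixel (stored; used to recompute
#'   `area_mm2` on read).
#' @return `read_annotations_geojson()` returns an
#'   [annotation_regions()] tibble.
#' @export
write_annotations_geojson <- function(regions, path, slide_id = "slide",
                                      mpp_x = NA_real_, mpp_y = mpp_x) {
  features <- purrr::map(seq_len(nrow(regions)), function(i) {
    list(
      type = "Feature",
      geometry = polygon_to_geojson(regions$polygon[[i]]),
      properties = list(category = regions$category[i])
    )
  })
  doc <- list(
    type = "FeatureCollection",
    properties = list(slide_id = slide_id, mpp_x = mpp_x, mpp_y = mpp_y),
    features = features
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' @rdname write_annotations_geojson
#' @export
read_annotations_geojson <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  mpp_x <- doc$properties$mpp_x %||% NA_real_
  mpp_y <- doc$properties$mpp_y %||% mpp_x
  polys <- purrr::map(doc$features, function(f) geojson_to_polygon(f$geometry))
  cats <- purrr::map_chr(doc$features, function(f) f$properties$category)
  if (length(cats) == 0) {
    return(annotation_regions(character(), list(), mpp_x = mpp_x %||% 1))
  }
  annotation_regions(cats, polys, mpp_x = mpp_x, mpp_y = mpp_y)
}

#' Read and write segmentation GeoJSON
#'
#' Same dialect as annotations with an added per-feature `certainty`
#' property and slide metadata (tissue area, mpp) in the collection's
#' properties.
#'
#' @param seg A [slide_segmentation()].
#' @param path File path.
#' @return `read_segmentation_geojson()` returns a
#'   [slide_segmentation()].
#' @export
write_segmentation_geojson <- function(seg, path) {
  objs <- seg$objects
  features <- purrr::map(seq_len(nrow(objs)), function(i) {
    list(
      type = "Feature",
      geometry = polygon_to_geojson(objs$polygon[[i]]),
      properties = list(category = objs$category[i],
                        certainty = objs$certainty[i])
    )
  })
  doc <- list(
    type = "FeatureCollection",
    properties = list(
      slide_id = seg$slide_id,
      tissue_area_mm2 = seg$tissue_area_mm2,
      mpp_x = seg$mpp_x, mpp_y = seg$mpp_y
    ),
    features = features
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' @rdname write_segmentation_geojson
#' @export
read_segmentation_geojson <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  props <- doc$properties
  mpp_x <- props$mpp_x %||% NA_real_
  mpp_y <- props$mpp_y %||% mpp_x
  n <- length(doc$features)
  if (n == 0) {
    objs <- empty_objects()
  } else {
    polys <- purrr::map(doc$features,
                        function(f) geojson_to_polygon(f$geometry))
    area_px <- purrr::map_dbl(polys, polygon_area)
    objs <- tibble::tibble(
      object_id = seq_len(n),
      category = purrr::map_chr(doc$features,
                                function(f) f$properties$category),
      certainty = purrr::map_dbl(doc$features,
                                 function(f) f$properties$certainty),
      polygon = polys,
      area_px = area_px,
      area_mm2 = px_to_mm2(area_px, mpp_x, mpp_y),
      spurious = NA
    )
  }
  slide_segmentation(props$slide_id %||% "slide", objs,
                     props$tissue_area_mm2 %||% NA_real_, mpp_x, mpp_y)
}
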