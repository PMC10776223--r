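# GeoJSON read/write via jsonlite. Coordinates are written as-is (the
# pipeline works in a projected metric CRS; consumers that need WGS84 should
# reproject externally).

#' Write point features to GeoJSON
#'
#' @param points data frame with `x`, `y` plus any property columns.
#' @param path output file.
#' @export
geojson_write_points <- function(points, path) {
  props <- setdiff(names(points), c("x", "y"))
  feats <- lapply(seq_len(nrow(points)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])),
         properties = as.list(points[i, props, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read point features from GeoJSON
#'
#' @param path file path.
#' @return data frame with `x`, `y` and property columns.
#' @export
geojson_read_points <- function(path) {
  g <- jsonlite::read_json(path)
  feats <- g$features
  if (length(feats) == 0) return(data.frame(x = numeric(), y = numeric()))
  rows <- lapply(feats, function(f) {
    cc <- unlist(f$geometry$coordinates)
    c(list(x = cc[1], y = cc[2]), f$properties)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Write classed landcover polygons to GeoJSON
#'
#' @param polygons long data frame `poly_id, class, x, y` (ring vertices in
#'   order, unclosed).
#' @param path output file.
#' @export
geojson_write_polygons <- function(polygons, path) {
  ids <- unique(polygons$poly_id)
  feats <- lapply(ids, function(pid) {
    p <- polygons[polygons$poly_id == pid, , drop = FALSE]
    ring <- lapply(c(seq_len(nrow(p)), 1L), function(i) c(p$x[i], p$y[i]))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = list(poly_id = pid, class = p$class[1]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read classed landcover polygons from GeoJSON
#'
#' Supports Polygon and MultiPolygon features carrying a `class` property
#' (interior rings are not supported and raise an error).
#'
#' @param path file path.
#' @return long data frame `poly_id, class, x, y`.
#' @export
geojson_read_polygons <- function(path) {
  g <- jsonlite::read_json(path)
  out <- list()
  for (i in seq_along(g$features)) {
    f <- g$features[[i]]
    cl <- f$properties$class
    if (is.null(cl)) stop("polygon feature ", i, " lacks a 'class' property")
    pid <- if (!is.null(f$properties$poly_id)) f$properties$poly_id else
      sprintf("poly_%04d", i)
    geoms <- switch(f$geometry$type,
                    Polygon = list(f$geometry$coordinates),
                    MultiPolygon = f$geometry$coordinates,
                    stop("unsupported geometry type: ", f$geometry$type))
    for (k in seq_along(geoms)) {
      rings <- geoms[[k]]
      if (length(rings) > 1) stop("interior rings are not supported")
      ring <- rings[[1]]
      xy <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
      # drop the closing vertex
      if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ])) {
        xy <- xy[-nrow(xy), , drop = FALSE]
      }
      out[[length(out) + 1]] <- data.frame(
        poly_id = if (length(geoms) > 1) paste0(pid, "_", k) else pid,
        class = cl, x = xy[, 1], y = xy[, 2])
    }
  }
  if (length(out) == 0) {
    return(data.frame(poly_id = character(), class = character(),
                      x = numeric(), y = numeric()))
  }
  do.call(rbind, out)
}
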