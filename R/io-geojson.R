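#' GeoJSON input/output for rectilinear geometry
#'
#' Polygon layers are exchanged as RFC 7946 GeoJSON FeatureCollections.
#' Geometry is written as a MultiPolygon holding one rectangular ring per
#' rectangle of the normalized [rect_set()] (counter-clockwise, closed).
#' The reader accepts Polygon and MultiPolygon features whose rings are
#' axis-aligned rectangles — the only geometry this package computes with —
#' and rejects anything else with a clear error rather than silently
#' approximating.
#'
#' @param geoms named list of [rect_set()] geometries (names become feature
#'   ids via `id_field`).
#' @param properties data frame of per-feature properties, same order as
#'   `geoms`.
#' @param path file path.
#' @param id_field name of the property holding the feature id.
#' @return `write_geojson()` returns `path` invisibly; `read_geojson()`
#'   returns a list with `properties` (tibble) and `geoms` (list of rect
#'   sets).
#' @export
write_geojson <- function(geoms, properties, path, id_field = "unit_id") {
  if (length(geoms) != nrow(properties)) {
    abort_validation("write_geojson: %d geometries but %d property rows",
                     length(geoms), nrow(properties))
  }
  features <- lapply(seq_along(geoms), function(i) {
    r <- rs_normalize(geoms[[i]])
    polys <- lapply(seq_len(nrow(r)), function(k) {
      ring <- rbind(c(r$xmin[k], r$ymin[k]),
                    c(r$xmax[k], r$ymin[k]),
                    c(r$xmax[k], r$ymax[k]),
                    c(r$xmin[k], r$ymax[k]),
                    c(r$xmin[k], r$ymin[k]))
      list(ring)
    })
    props <- lapply(as.list(properties[i, , drop = FALSE]), function(v) {
      if (is.na(v)) NULL else jsonlite::unbox(v)
    })
    props <- props[!vapply(props, is.null, logical(1))]
    list(type = jsonlite::unbox("Feature"),
         properties = props,
         geometry = list(type = jsonlite::unbox("MultiPolygon"),
                         coordinates = polys))
  })
  fc <- list(type = jsonlite::unbox("FeatureCollection"), features = features)
  write_atomic(path, function(tmp) {
    jsonlite::write_json(fc, tmp, digits = NA, auto_unbox = FALSE,
                         null = "null", pretty = FALSE)
  })
  invisible(path)
}

ring_to_rect <- function(ring) {
  m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  if (nrow(m) < 4) abort_io("GeoJSON ring with fewer than 4 points")
  if (all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  xs <- sort(unique(m[, 1])); ys <- sort(unique(m[, 2]))
  if (nrow(m) != 4 || length(xs) != 2 || length(ys) != 2) {
    abort_io("GeoJSON ring is not an axis-aligned rectangle")
  }
  c(xmin = xs[1], ymin = ys[1], xmax = xs[2], ymax = ys[2])
}

geom_to_rect_set <- function(geom) {
  ty <- geom$type
  polys <- switch(ty,
    Polygon = list(geom$coordinates),
    MultiPolygon = geom$coordinates,
    abort_io("unsupported GeoJSON geometry type '%s'", ty))
  rects <- lapply(polys, function(poly) {
    if (length(poly) != 1L) {
      abort_io("GeoJSON polygons with interior rings (holes) are not supported")
    }
    ring_to_rect(poly[[1]])
  })
  m <- do.call(rbind, rects)
  rs_normalize(rect_set(m[, "xmin"], m[, "ymin"], m[, "xmax"], m[, "ymax"]))
}

#' @rdname write_geojson
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) abort_io("GeoJSON file not found: %s", path)
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(fc$type, "FeatureCollection")) {
    abort_io("%s: not a GeoJSON FeatureCollection", path)
  }
  feats <- fc$features
  geoms <- lapply(feats, function(f) geom_to_rect_set(f$geometry))
  props <- lapply(feats, function(f) {
    p <- f$properties
    lapply(p, function(v) if (is.null(v)) NA else v)
  })
  keys <- unique(unlist(lapply(props, names)))
  tab <- tibble::as_tibble(
    stats::setNames(lapply(keys, function(k) {
      vals <- lapply(props, function(p) p[[k]] %||% NA)
      unlist(vals)
    }), keys))
  list(properties = tab, geoms = geoms)
}
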