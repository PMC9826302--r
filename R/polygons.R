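#' Labeled polygon sets (botanical countries, ISO countries, regions)
#'
#' A `region_set` is a list of coded polygons in WGS84.  Each element has
#' a `code` (e.g. a TDWG level-3 code) and one or more `rings`, each a
#' two-column matrix of lon/lat vertices (outer rings only; the layers
#' used here carry no holes).  Point lookups test polygons in
#' lexicographic code order and return the first containing polygon, so a
#' point lying exactly on a shared boundary is deterministically assigned
#' to the polygon with the smallest code.
#'
#' @param polygons list of elements with fields `code` and `rings`.
#' @return An object of class `region_set`.
#' @export
region_set <- function(polygons) {
  if (length(polygons) == 0) stop("empty polygon set")
  codes <- vapply(polygons, function(p) as.character(p$code), character(1))
  if (anyNA(codes) || any(!nzchar(codes)))
    stop("every polygon needs a non-empty code")
  polygons <- polygons[order(codes)]
  structure(polygons, class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d polygons: %s\n", length(x),
              paste(utils::head(region_codes(x), 8), collapse = ", ")))
  invisible(x)
}

#' @rdname region_set
#' @param x a `region_set`.
#' @export
region_codes <- function(x) {
  vapply(x, function(p) p$code, character(1))
}

#' Build a region set from axis-aligned rectangles
#'
#' Convenience constructor used heavily by the synthetic-data generator
#' ("botanical countries" as rectangles).
#'
#' @param codes character vector of region codes.
#' @param xmin,xmax,ymin,ymax rectangle bounds, recycled against `codes`.
#' @export
rect_regions <- function(codes, xmin, xmax, ymin, ymax) {
  n <- length(codes)
  d <- data.frame(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
  region_set(lapply(seq_len(n), function(i) {
    r <- d[i, ]
    list(code = codes[i],
         rings = list(cbind(c(r$xmin, r$xmax, r$xmax, r$xmin, r$xmin),
                            c(r$ymin, r$ymin, r$ymax, r$ymax, r$ymin))))
  }))
}

#' Read polygons from GeoJSON
#'
#' Supports FeatureCollections of Polygon / MultiPolygon features; only
#' outer rings are used.
#'
#' @param path GeoJSON file.
#' @param code_property name of the feature property holding the region
#'   code.
#' @export
read_geojson_regions <- function(path, code_property = "code") {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  polys <- lapply(feats, function(f) {
    code <- f$properties[[code_property]]
    if (is.null(code)) stop("feature lacks property '", code_property, "'")
    geom <- f$geometry
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    rings <- switch(geom$type,
      Polygon = list(ring_mat(geom$coordinates[[1]])),
      MultiPolygon = lapply(geom$coordinates, function(p) ring_mat(p[[1]])),
      stop("unsupported geometry type: ", geom$type))
    list(code = as.character(code), rings = rings)
  })
  region_set(polys)
}

#' Write a region set to GeoJSON
#'
#' @param regions a [region_set()].
#' @param path output file.
#' @param code_property property name for the code.
#' @export
write_geojson_regions <- function(regions, path, code_property = "code") {
  feats <- lapply(regions, function(p) {
    coords <- lapply(p$rings, function(r)
      list(lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))))
    props <- stats::setNames(list(p$code), code_property)
    list(type = "Feature", properties = props,
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Locate points in a region set
#'
#' @param regions a [region_set()].
#' @param lon,lat point coordinates, decimal degrees WGS84.
#' @return character vector of region codes; `NA` for points contained in
#'   no polygon.  Boundary points count as inside; overlaps resolve to the
#'   lexicographically smallest code.
#' @export
locate_regions <- function(regions, lon, lat) {
  stopifnot(inherits(regions, "region_set"))
  out <- rep(NA_character_, length(lon))
  todo <- !is.na(lon) & !is.na(lat)
  for (p in regions) {          # already in lexicographic code order
    if (!any(todo)) break
    for (ring in p$rings) {
      hit <- todo
      hit[todo] <- sp::point.in.polygon(lon[todo], lat[todo],
                                        ring[, 1], ring[, 2]) > 0
      out[hit] <- p$code
      todo <- todo & !hit
    }
  }
  out
}
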