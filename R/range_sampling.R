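#' Sampling-effort grids, Jenks classes, hotspots and range metrics
#'
#' @name range-and-sampling
NULL

#' Per-cell record counts on a degree grid
#'
#' Counts records in half-open cells anchored at integer multiples of
#' `cell_size` (a record sitting exactly on a cell corner belongs to the
#' cell north-east of it under the half-open convention).
#'
#' @param records occurrence data.frame.
#' @param cell_size cell edge in degrees (default 1).
#' @param extent optional `c(xmin, xmax, ymin, ymax)`; defaults to the
#'   snug integer-degree extent of the records.  Records outside are
#'   counted in `n_outside`.
#' @param region label for the counted region.
#' @return object of class `grid_counts`: a count [clim_grid()] (`grid`),
#'   `region`, `n_records` (in-extent), `n_outside`.
#' @export
grid_counts <- function(records, cell_size = 1, extent = NULL,
                        region = "all") {
  lon <- records$longitude; lat <- records$latitude
  anchor <- function(v) floor(v / cell_size) * cell_size
  if (is.null(extent))
    extent <- c(anchor(min(lon)), anchor(max(lon)) + cell_size,
                anchor(min(lat)), anchor(max(lat)) + cell_size)
  ncol <- round((extent[2] - extent[1]) / cell_size)
  nrow <- round((extent[4] - extent[3]) / cell_size)
  g <- clim_grid(matrix(0, nrow, ncol), extent[1], extent[3], cell_size)
  ix <- cell_index(g, lon, lat)
  inside <- ix$inside
  tab <- table(paste(ix$row[inside], ix$col[inside]))
  rc <- do.call(rbind, strsplit(names(tab), " "))
  g$values[cbind(as.integer(rc[, 1]), as.integer(rc[, 2]))] <-
    as.numeric(tab)
  structure(list(grid = g, region = region,
                 n_records = sum(inside), n_outside = sum(!inside)),
            class = "grid_counts")
}

#' @export
print.grid_counts <- function(x, ...) {
  cat(sprintf("<grid_counts> region '%s': %d records in %d occupied cells (max %g)\n",
              x$region, x$n_records, sum(x$grid$values > 0, na.rm = TRUE),
              max(x$grid$values, na.rm = TRUE)))
  invisible(x)
}

seg_ssd <- function(cs, cs2, a, b) {
  # within-segment sum of squared deviations of sorted values a..b,
  # from prefix sums cs (values) and cs2 (squares)
  n <- b - a + 1
  s <- cs[b + 1] - cs[a]
  (cs2[b + 1] - cs2[a]) - s * s / n
}

#' Fisher–Jenks natural breaks
#'
#' Exact optimal partition of a 1-D value set into `k` contiguous
#' classes minimizing the total within-class sum of squared deviations
#' (dynamic programming over the sorted values, `O(k n^2)`).  When
#' several partitions tie, the one whose last class starts lowest is
#' returned.
#'
#' @param values numeric vector (e.g. nonzero cell counts).
#' @param k number of classes; must not exceed the number of distinct
#'   values.
#' @return object of class `jenks_classification`: `k`,
#'   `breaks` (length `k + 1`: data minimum then each class maximum),
#'   `classes` (data.frame `class`, `min`, `max`, `n`), `ssd` (total
#'   within-class sum of squared deviations), `assignment` (class index
#'   per input value, original order).
#' @export
jenks_breaks <- function(values, k) {
  stopifnot(k >= 1)
  if (k > length(unique(values)))
    stop("k (", k, ") exceeds the number of distinct values (",
         length(unique(values)), ")")
  x <- sort(values)
  n <- length(x)
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  # cost[i, j]: optimal SSD of x[1..i] split into j classes
  cost <- matrix(Inf, n, k)
  back <- matrix(0L, n, k)
  cost[, 1] <- vapply(seq_len(n), function(i) seg_ssd(cs, cs2, 1, i),
                      numeric(1))
  if (k > 1) for (j in 2:k) {
    for (i in j:n) {
      s <- (j - 1):(i - 1)          # last class = x[(s+1)..i]
      tot <- cost[s, j - 1] +
        vapply(s, function(si) seg_ssd(cs, cs2, si + 1, i), numeric(1))
      best <- which(tot <= min(tot) + 1e-12)[1]   # ties: earliest split,
      cost[i, j] <- tot[best]                     # i.e. lowest last-class min
      back[i, j] <- s[best]
    }
  }
  bounds <- integer(k + 1)
  bounds[k + 1] <- n
  if (k > 1) for (j in k:2) bounds[j] <- back[bounds[j + 1], j]
  bounds[1] <- 0L
  classes <- data.frame(
    class = seq_len(k),
    min = x[bounds[-(k + 1)] + 1],
    max = x[bounds[-1]],
    n = diff(bounds))
  brks <- c(x[1], classes$max)
  assignment <- findInterval(values, classes$min, left.open = FALSE)
  assignment <- pmin(pmax(assignment, 1L), k)
  structure(list(k = k, breaks = brks, classes = classes,
                 ssd = cost[n, k], assignment = assignment),
            class = "jenks_classification")
}

#' @export
print.jenks_classification <- function(x, ...) {
  cat(sprintf("<jenks_classification> k = %d, SSD = %g\n", x$k, x$ssd))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

#' Sampling hotspots among Jenks cell categories
#'
#' A cell category is a sampling hotspot when its count range reaches
#' 25% (by default) of the region's per-cell maximum.  The threshold is
#' reported both raw (`frac * max`) and as the next integer record count
#' (its ceiling); a class is flagged when its class maximum is at least
#' the integer threshold.  Hotspot flags are therefore monotone: every
#' class above a flagged class is flagged.
#'
#' @param grid a [grid_counts()].
#' @param classes a [jenks_breaks()] classification of the grid's
#'   nonzero counts.
#' @param frac hotspot fraction of the per-cell maximum (default 0.25).
#' @return list: `max_count`, `threshold` (raw), `threshold_records`
#'   (integer), `classes` (the class table with a `hotspot` flag).
#' @export
hotspot_categories <- function(grid, classes, frac = 0.25) {
  stopifnot(inherits(grid, "grid_counts"),
            inherits(classes, "jenks_classification"))
  mx <- max(grid$grid$values, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) stop("empty sampling grid")
  thr <- frac * mx
  thr_int <- ceiling(thr)
  cls <- classes$classes
  cls$hotspot <- cls$max >= thr_int
  list(max_count = mx, threshold = thr, threshold_records = thr_int,
       classes = cls)
}

# authalic-sphere cylindrical equal-area forward projection (meters)
cea_project <- function(lon, lat, R = 6371007.2) {
  cbind(x = R * lon * pi / 180, y = R * sin(lat * pi / 180))
}

#' Area of occupancy (AOO)
#'
#' Projects points to a world cylindrical equal-area grid of
#' `cell_width_km`-wide square cells (fixed origin, default at the
#' projected (0, 0)) and counts occupied cells; the AOO is the occupied
#' count times the cell area (4 km² for the default 2-km mesh).  The
#' result depends on the grid origin for point pairs straddling a grid
#' line; the origin is fixed (and configurable) for reproducibility.
#'
#' @param lon,lat point coordinates, decimal degrees.
#' @param cell_width_km grid mesh (default 2 km).
#' @param origin_km grid origin offset `c(x, y)` in km.
#' @return AOO in km² (a multiple of `cell_width_km^2`).
#' @export
aoo <- function(lon, lat, cell_width_km = 2, origin_km = c(0, 0)) {
  stopifnot(length(lon) >= 1, length(lon) == length(lat))
  xy <- cea_project(lon, lat) / 1000
  cells <- paste(floor((xy[, 1] - origin_km[1]) / cell_width_km),
                 floor((xy[, 2] - origin_km[2]) / cell_width_km))
  length(unique(cells)) * cell_width_km^2
}

#' Extent of occurrence (EOO)
#'
#' Geodesic area (WGS84 ellipsoid) of the convex hull around all
#' occurrences.  Fewer than three non-collinear points give 0.  Point
#' sets spanning the antimeridian are unwrapped (negative longitudes
#' shifted by 360) when their raw longitude spread exceeds 180 degrees,
#' so trans-Pacific disjunct ranges get the hull of the compact
#' configuration rather than one wrapped the long way around.
#'
#' @param lon,lat point coordinates, decimal degrees.
#' @return EOO in km².
#' @export
eoo <- function(lon, lat) {
  stopifnot(length(lon) >= 1, length(lon) == length(lat))
  pts <- unique(cbind(lon, lat))
  if (nrow(pts) < 3) return(0)
  if (diff(range(pts[, 1])) > 180) {
    pts[, 1] <- ifelse(pts[, 1] < 0, pts[, 1] + 360, pts[, 1])
    if (diff(range(pts[, 1])) > 180) pts[, 1] <- ifelse(pts[, 1] >= 360,
                                                        pts[, 1] - 360,
                                                        pts[, 1])
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3) return(0)
  hull <- pts[h, , drop = FALSE]
  area <- abs(geosphere::areaPolygon(hull)) / 1e6
  # collinear hulls can return a numerically tiny but nonzero area
  if (area < 1e-6) 0 else area
}

#' Range-size class from the AOO
#'
#' Restricted below `restricted_max_km2` (strict; the 2000 km² bound is
#' the minimum area of occupancy of IUCN criterion B2 for the Vulnerable
#' category, used purely as an objective size cutoff, not as a risk
#' assessment), widespread strictly above `widespread_min_km2`,
#' intermediate between.
#'
#' @param aoo_km2 area of occupancy in km².
#' @param restricted_max_km2 restricted/intermediate bound (default 2000).
#' @param widespread_min_km2 intermediate/widespread bound (default 10000).
#' @return character vector of class labels.
#' @export
range_size_class <- function(aoo_km2, restricted_max_km2 = 2000,
                             widespread_min_km2 = 10000) {
  ifelse(aoo_km2 < restricted_max_km2, "restricted",
         ifelse(aoo_km2 > widespread_min_km2, "widespread",
                "intermediate"))
}

#' Range metrics for every genus
#'
#' @param records occurrence data.frame.
#' @param ... passed to [aoo()] / [range_size_class()].
#' @return data.frame `genus`, `n`, `aoo_km2`, `eoo_km2`, `size_class`.
#' @export
range_metrics <- function(records, ...) {
  rows <- lapply(split(records, records$genus), function(df) {
    a <- aoo(df$longitude, df$latitude, ...)
    data.frame(genus = df$genus[1], n = nrow(df), aoo_km2 = a,
               eoo_km2 = eoo(df$longitude, df$latitude),
               size_class = range_size_class(a), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Temporal accumulation of records
#'
#' Cumulative record counts per year for each region and qualitative
#' label, starting at `start_year` (earlier or undated records are
#' excluded and counted), with the first year at which each cumulative
#' fraction (default quartiles 25/50/75%) is reached.
#'
#' @param records occurrence data.frame with `year`.
#' @param regions a [region_set()] partitioning the study area; records
#'   are assigned by point-in-polygon.
#' @param labels named character vector genus -> label.
#' @param start_year first usable collection year (default 1900).
#' @param fractions cumulative fractions to locate.
#' @return list: `series` (data.frame `year`, `region`, `label`, `n`,
#'   `cumulative`), `quantile_years` (data.frame `region`, `label`,
#'   `fraction`, `year`), `n_excluded`.
#' @export
temporal_series <- function(records, regions, labels, start_year = 1900,
                            fractions = c(0.25, 0.5, 0.75)) {
  usable <- !is.na(records$year) & records$year >= start_year
  n_excl <- sum(!usable)
  rec <- records[usable, , drop = FALSE]
  rec$region <- locate_regions(regions, rec$longitude, rec$latitude)
  rec$label <- unname(labels[rec$genus])
  rec <- rec[!is.na(rec$region) & !is.na(rec$label), , drop = FALSE]
  years <- start_year:max(rec$year)
  series <- list(); qrows <- list()
  for (grp in split(rec, paste(rec$region, rec$label, sep = "\r"))) {
    n_by_year <- table(factor(grp$year, levels = years))
    cum <- cumsum(as.integer(n_by_year))
    series[[length(series) + 1]] <- data.frame(
      year = years, region = grp$region[1], label = grp$label[1],
      n = as.integer(n_by_year), cumulative = cum,
      stringsAsFactors = FALSE)
    total <- nrow(grp)
    for (f in fractions)
      qrows[[length(qrows) + 1]] <- data.frame(
        region = grp$region[1], label = grp$label[1], fraction = f,
        year = years[which(cum >= f * total)[1]],
        stringsAsFactors = FALSE)
  }
  list(series = do.call(rbind, series),
       quantile_years = do.call(rbind, qrows),
       n_excluded = n_excl)
}

#' Genus richness per spatial unit
#'
#' Distinct-genus counts per TDWG botanical country, with a composition
#' label from the qualitative tropical/temperate map: `"temperate-only"`,
#' `"tropical-only"`, `"both"`, or `"none"` for empty units.
#'
#' @param records occurrence data.frame with `country_code_tdwg` filled.
#' @param units character vector of unit codes, or a [region_set()].
#' @param labels named character vector genus -> label.
#' @return data.frame `unit`, `n_genera`, `composition`.
#' @export
richness_by_unit <- function(records, units, labels) {
  codes <- if (inherits(units, "region_set")) region_codes(units)
    else as.character(units)
  rows <- lapply(codes, function(u) {
    gen <- unique(records$genus[!is.na(records$country_code_tdwg) &
                                  records$country_code_tdwg == u])
    labs <- unique(unname(labels[gen]))
    comp <- if (length(gen) == 0) "none"
      else if (setequal(labs, "temperate")) "temperate-only"
      else if (setequal(labs, "tropical")) "tropical-only"
      else "both"
    data.frame(unit = u, n_genera = length(gen), composition = comp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
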