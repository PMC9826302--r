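#' Categorical bioclimatic regionalizations
#'
#' A `regionalization` couples a [clim_grid()] of integer category codes
#' with a legend (code -> category label) and a name.  Five
#' classification systems are supported: the latitudinal zonation and the
#' Holdridge biotemperature life zones are built by this package;
#' aggregated Köppen–Geiger main classes, GEnS broad biomes and
#' simplified ecoregion biomes are consumed as supplied categorical
#' layers (with [koppen_aggregate()] / [ecoregion_simplify()] available
#' to reduce full legends to the broad classes).
#'
#' @param grid a [clim_grid()] of integer category codes.
#' @param legend named character vector mapping code (as character) to
#'   category label; every non-NoData cell value must have an entry.
#' @param name classification label.
#' @export
regionalization <- function(grid, legend, name) {
  stopifnot(inherits(grid, "clim_grid"), is.character(legend),
            !is.null(names(legend)))
  codes <- unique(grid$values[!is.na(grid$values)])
  miss <- setdiff(as.character(codes), names(legend))
  if (length(miss))
    stop("cell values without a legend entry: ", paste(miss, collapse = ", "))
  structure(list(grid = grid, legend = legend, name = name),
            class = "regionalization")
}

#' @export
print.regionalization <- function(x, ...) {
  cat(sprintf("<regionalization> '%s': %d categories\n", x$name,
              length(x$legend)))
  print(x$grid)
  invisible(x)
}

#' Read/write a regionalization as ASCII grid + JSON legend sidecar
#'
#' @param x a [regionalization()].
#' @param path `.asc` path; the legend is stored next to it as
#'   `<path>.legend.json` (fields `name`, `legend`).
#' @export
write_regionalization <- function(x, path) {
  write_ascii_grid(x$grid, path)
  jsonlite::write_json(list(name = x$name, legend = as.list(x$legend)),
                       paste0(path, ".legend.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_regionalization
#' @export
read_regionalization <- function(path) {
  g <- read_ascii_grid(path)
  side <- jsonlite::read_json(paste0(path, ".legend.json"))
  regionalization(g, unlist(side$legend), side$name)
}

#' Twelve co-registered monthly mean-temperature grids
#'
#' @param grids list of exactly 12 [clim_grid()]s (January..December,
#'   degrees C) sharing one grid definition, with aligned NoData cells.
#' @export
monthly_temperature <- function(grids) {
  if (length(grids) != 12)
    stop("monthly temperature needs exactly 12 grids, got ", length(grids))
  ref <- grids[[1]]
  same <- function(g) inherits(g, "clim_grid") &&
    isTRUE(all.equal(c(g$xmin, g$ymin, g$cellsize, g$nrow, g$ncol),
                     c(ref$xmin, ref$ymin, ref$cellsize, ref$nrow, ref$ncol)))
  if (!all(vapply(grids, same, logical(1))))
    stop("monthly grids are not co-registered")
  na_ref <- is.na(ref$values)
  for (g in grids)
    if (!identical(is.na(g$values), na_ref))
      stop("NoData cells are not aligned across months")
  structure(grids, class = "monthly_temperature")
}

#' Biotemperature grid
#'
#' Biotemperature is the mean over the 12 months of the monthly mean
#' temperature clamped to the range in which plants grow efficiently:
#' values below 0 degC or above 30 degC are replaced by 0 before
#' averaging.  The result is therefore bounded in \[0, 30\] everywhere.
#'
#' @param monthly a [monthly_temperature()].
#' @return a [clim_grid()] of biotemperature (degC); NoData cells
#'   propagate.
#' @export
biotemperature <- function(monthly) {
  if (!inherits(monthly, "monthly_temperature"))
    monthly <- monthly_temperature(monthly)
  acc <- matrix(0, monthly[[1]]$nrow, monthly[[1]]$ncol)
  for (g in monthly) {
    v <- g$values
    v[!is.na(v) & (v < 0 | v > 30)] <- 0
    acc <- acc + v
  }
  clim_grid(acc / 12, monthly[[1]]$xmin, monthly[[1]]$ymin,
            monthly[[1]]$cellsize)
}

holdridge_zones <- c("polar", "subpolar", "boreal", "cool temperate",
                     "warm temperate", "subtropical", "tropical")
# lower bounds of the zones above; each zone is [lower, next lower), the
# warmest is [24, 30].  The published interval table prints an
# overlapping boreal/subpolar boundary (6-3 vs 3.5-1.5); a partition
# requires contiguity, so 3 is used as the boreal lower bound.
holdridge_lower <- c(0, 1.5, 3, 6, 12, 17, 24)

#' Holdridge life-zone classification of biotemperature
#'
#' Assigns each biotemperature value to one of seven latitudinal world
#' life zones.  Intervals are closed at the lower bound of the warmer
#' class: tropical \[24, 30\], subtropical \[17, 24), warm temperate
#' \[12, 17), cool temperate \[6, 12), boreal \[3, 6), subpolar
#' \[1.5, 3), polar \[0, 1.5).  Note the published interval table shows
#' boreal and subpolar as overlapping (6–3 vs 3.5–1.5); the contiguous
#' bounds \[3, 6) / \[1.5, 3) are used so the zones partition \[0, 30\].
#'
#' @param biot numeric biotemperature values in \[0, 30\]; `NA` passes
#'   through.
#' @return character vector of zone labels.
#' @export
holdridge_classify <- function(biot) {
  ok <- is.na(biot) | (biot >= 0 & biot <= 30)
  if (!all(ok))
    stop("biotemperature outside [0, 30]: ",
         paste(utils::head(biot[!ok]), collapse = ", "))
  idx <- findInterval(biot, holdridge_lower)
  out <- holdridge_zones[idx]
  out[is.na(biot)] <- NA_character_
  out
}

latitudinal_zones <- c("tropical", "subtropical", "temperate", "polar")

#' Latitudinal climate zonation
#'
#' Pure-latitude zonation, symmetric about the equator: tropical for
#' absolute latitude below 23.5 degrees, subtropical in \[23.5, 40),
#' temperate in \[40, 66.5), polar at and above 66.5 degrees.
#'
#' @param latitude decimal degrees in \[-90, 90\]; `NA` passes through.
#' @return character vector of zone labels.
#' @export
latitudinal_classify <- function(latitude) {
  ok <- is.na(latitude) | (latitude >= -90 & latitude <= 90)
  if (!all(ok)) stop("latitude outside [-90, 90]")
  a <- abs(latitude)
  idx <- findInterval(a, c(0, 23.5, 40, 66.5))
  out <- latitudinal_zones[idx]
  out[is.na(latitude)] <- NA_character_
  out
}

#' Aggregate Köppen–Geiger codes to main classes
#'
#' Reduces full Köppen–Geiger class codes to six broad classes: tropical
#' (A), dry (B), temperate (C), continental (D), tundra (ET) and polar
#' frost (EF).  The polar group E carries its two subtypes as distinct
#' broad classes, matching the tundra/frost split.
#'
#' @param code character vector of Köppen–Geiger codes (e.g. `"Af"`,
#'   `"Cfb"`, `"ET"`); `NA` passes through.
#' @return character vector of main-class labels.
#' @export
koppen_aggregate <- function(code) {
  out <- rep(NA_character_, length(code))
  first <- substr(code, 1, 1)
  out[first == "A"] <- "tropical"
  out[first == "B"] <- "dry"
  out[first == "C"] <- "temperate"
  out[first == "D"] <- "continental"
  out[!is.na(code) & code == "ET"] <- "tundra"
  out[!is.na(code) & code == "EF"] <- "polar"
  bad <- !is.na(code) & is.na(out)
  if (any(bad))
    stop("unknown Köppen–Geiger code(s): ",
         paste(unique(code[bad]), collapse = ", "))
  out
}

ecoregion_tropical <- c(
  "tropical and subtropical dry broadleaf forests",
  "tropical and subtropical moist broadleaf forests",
  "tropical and subtropical coniferous forests",
  "tropical and subtropical grasslands, savannas, and shrublands")
ecoregion_temperate <- c(
  "temperate broadleaf and mixed forests",
  "temperate conifer forests",
  "temperate grasslands, savannas, and shrublands")
ecoregion_other <- c(
  "boreal forests/taiga", "deserts and xeric shrublands",
  "flooded grasslands and savannas", "mangroves",
  "mediterranean forests, woodlands, and scrub",
  "montane grasslands and shrublands", "tundra")

#' Simplify ecoregion biomes
#'
#' Collapses the 14 terrestrial ecoregion biomes into a reduced legend:
#' the four tropical/subtropical forest-and-grassland biomes merge into
#' "tropical and subtropical", the three temperate ones into
#' "temperate", and the remaining seven biomes pass through unchanged
#' (9 output categories).
#'
#' @param biome_name character vector of biome names (case-insensitive);
#'   `NA` passes through.
#' @return character vector of simplified category labels.
#' @export
ecoregion_simplify <- function(biome_name) {
  key <- tolower(trimws(biome_name))
  out <- rep(NA_character_, length(key))
  out[key %in% ecoregion_tropical] <- "tropical and subtropical"
  out[key %in% ecoregion_temperate] <- "temperate"
  pass <- key %in% ecoregion_other
  out[pass] <- biome_name[pass]
  bad <- !is.na(biome_name) & is.na(out)
  if (any(bad))
    stop("unknown biome(s): ", paste(unique(biome_name[bad]),
                                     collapse = "; "))
  out
}

#' Build the latitudinal-zonation raster
#'
#' Classifies each cell by the latitude of its center.
#'
#' @param def a [grid_def()].
#' @return a [regionalization()] named `"latitudinal"`.
#' @export
build_latitudinal_raster <- function(def) {
  g <- empty_grid(def)
  lat <- g$ymin + (g$nrow - seq_len(g$nrow) + 0.5) * g$cellsize
  zone <- latitudinal_classify(lat)
  g$values <- matrix(match(zone, latitudinal_zones), g$nrow, g$ncol)
  legend <- stats::setNames(latitudinal_zones,
                            as.character(seq_along(latitudinal_zones)))
  regionalization(g, legend, "latitudinal")
}

#' Build the Holdridge life-zone raster
#'
#' Composes [biotemperature()] and [holdridge_classify()] per cell;
#' NoData propagates.
#'
#' @param monthly a [monthly_temperature()].
#' @return a [regionalization()] named `"holdridge"`.
#' @export
build_holdridge_raster <- function(monthly) {
  biot <- biotemperature(monthly)
  zone <- holdridge_classify(as.vector(biot$values))
  biot$values <- matrix(match(zone, holdridge_zones), biot$nrow, biot$ncol)
  legend <- stats::setNames(holdridge_zones,
                            as.character(seq_along(holdridge_zones)))
  regionalization(biot, legend, "holdridge")
}

#' Assign points to the categories of a regionalization
#'
#' Samples the layer at each point (half-open cell membership).  Points
#' in NoData cells or outside the grid extent are reported as
#' `"unclassified"`.
#'
#' @param lon,lat point coordinates, decimal degrees WGS84.
#' @param layer a [regionalization()].
#' @return character vector of category labels, with attribute
#'   `n_unclassified`.
#' @export
sample_regionalization <- function(lon, lat, layer) {
  stopifnot(inherits(layer, "regionalization"))
  v <- grid_extract(layer$grid, lon, lat)
  out <- ifelse(is.na(v), "unclassified",
                layer$legend[as.character(v)])
  attr(out, "n_unclassified") <- sum(out == "unclassified")
  out
}
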