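# Independent oracles and small fixture builders used across the suite.

# Exhaustive Fisher-Jenks oracle: minimum total within-class SSD over all
# contiguous partitions of the sorted values into k classes.
jenks_oracle_ssd <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  ssd <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(ssd(x))
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (j in seq_len(ncol(splits))) {
    b <- c(0, splits[, j], n)
    tot <- sum(vapply(seq_len(k),
                      function(i) ssd(x[(b[i] + 1):b[i + 1]]), numeric(1)))
    if (tot < best) best <- tot
  }
  best
}

# Ellipsoidal-surface area of a lon/lat-aligned rectangle by numerical
# integration of the WGS84 area element M(phi) * N(phi) * cos(phi).
wgs84_rect_area_km2 <- function(lon_range, lat_range) {
  a <- 6378137
  f <- 1 / 298.257223563
  e2 <- f * (2 - f)
  el <- function(phi_deg) {
    phi <- phi_deg * pi / 180
    s2 <- sin(phi)^2
    M <- a * (1 - e2) / (1 - e2 * s2)^1.5
    N <- a / sqrt(1 - e2 * s2)
    M * N * cos(phi)
  }
  dlam <- diff(lon_range) * pi / 180
  band <- stats::integrate(el, lat_range[1], lat_range[2],
                           rel.tol = 1e-10)$value * pi / 180
  dlam * band / 1e6
}

# one-category constant regionalization over a grid
constant_layer <- function(label = "tropical", def = grid_def(0, 0, 4, 4, 1)) {
  g <- clim_grid(matrix(1, def$nrow, def$ncol), def$xmin, def$ymin,
                 def$cellsize)
  regionalization(g, c("1" = label), "constant")
}

# two-band layer: cells south of `split_lat` are zone A, north zone B
band_layer <- function(split_lat, def = grid_def(0, 0, 10, 10, 1),
                       labels = c("south", "north")) {
  g <- clim_grid(matrix(NA_real_, def$nrow, def$ncol), def$xmin,
                 def$ymin, def$cellsize)
  lat <- def$ymin + (def$nrow - seq_len(def$nrow) + 0.5) * def$cellsize
  g$values <- matrix(ifelse(lat < split_lat, 1, 2), def$nrow, def$ncol)
  regionalization(g, stats::setNames(labels, c("1", "2")), "band")
}

# minimal occurrence data.frame from coordinates
toy_records <- function(lon, lat, genus = "GenusA", year = 2000,
                        locality = "forest", tdwg = NA_character_,
                        species = paste(genus, "alpha"),
                        catalog = sprintf("C%03d", seq_along(lon)),
                        lon_text = sprintf("%.4f", lon),
                        lat_text = sprintf("%.4f", lat),
                        source = "GBIF") {
  n <- length(lon)
  data.frame(
    record_id = sprintf("T-%03d", seq_len(n)),
    genus = rep_len(genus, n), species = rep_len(species, n),
    year = rep_len(as.integer(year), n),
    country_code_iso = NA_character_,
    country_code_tdwg = rep_len(tdwg, n),
    locality = rep_len(locality, n),
    longitude_text = lon_text, latitude_text = lat_text,
    longitude = lon, latitude = lat,
    elevation = 100, catalog_number = rep_len(catalog, n),
    basis_of_record = "PRESERVED_SPECIMEN",
    source = rep_len(source, n), stringsAsFactors = FALSE)
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}
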