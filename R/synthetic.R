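#' Seeded synthetic inputs with planted ground truth
#'
#' The generator emits every input the pipeline consumes — multi-source
#' occurrence tables, monthly temperature grids, categorical land masks
#' and rectangular "botanical country" polygons — with a withheld truth
#' table marking which records carry which planted defect.  Planted
#' defect classes are disjoint (a record has at most one defect) so that
#' each cleaning stage's removal count is identifiable and must match
#' the planted count exactly.
#'
#' @name synthetic-data
NULL

#' Scenario description for the occurrence generator
#'
#' Defaults give a compact desk-scale scenario: 100 records over 5
#' genera on a 6x6-degree landmass of four botanical countries
#' surrounded by 1 degree of sea, with 10 planted replicates, 5
#' low-precision records, 4 coastal records within 10 km of land, 3
#' offshore errors beyond 10 km, 2 cultivated-keyword records and 4
#' records outside the native range.
#'
#' @param seed integer seed.
#' @param n_genera number of genera.
#' @param n_records total rows emitted (clean + planted).
#' @param n_duplicates,n_low_precision,n_coastal,n_offshore,n_cultivated,n_out_of_range
#'   planted counts per defect class.
#' @param extent `c(xmin, xmax, ymin, ymax)` of the world.
#' @param land_margin sea width between the world edge and land.
#' @param land_cellsize resolution of the land-mask template (degrees).
#' @export
synthetic_scenario <- function(seed = 1, n_genera = 5, n_records = 100,
                               n_duplicates = 10, n_low_precision = 5,
                               n_coastal = 4, n_offshore = 3,
                               n_cultivated = 2, n_out_of_range = 4,
                               extent = c(0, 8, 0, 8), land_margin = 1,
                               land_cellsize = 0.05) {
  n_err <- n_duplicates + n_low_precision + n_coastal + n_offshore +
    n_cultivated + n_out_of_range
  if (n_err > n_records)
    stop("more planted errors (", n_err, ") than records (", n_records, ")")
  structure(list(seed = seed, n_genera = n_genera, n_records = n_records,
                 n_duplicates = n_duplicates,
                 n_low_precision = n_low_precision, n_coastal = n_coastal,
                 n_offshore = n_offshore, n_cultivated = n_cultivated,
                 n_out_of_range = n_out_of_range, extent = extent,
                 land_margin = land_margin, land_cellsize = land_cellsize),
            class = "synthetic_scenario")
}

#' Synthetic region layers: botanical countries, ISO country, land mask
#'
#' Tiles the land part of the scenario extent with a 2x2 layout of
#' rectangular TDWG-like botanical countries (codes `AAA`, `AAB`, `ABA`,
#' `ABB`), one ISO-like country (`ZA`) covering all land, and a land
#' template grid whose data cells are the cells with centers on land.
#' Fully deterministic for a given scenario.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `tdwg` and `iso` ([region_set()]s), `land`
#'   (a [clim_grid()] land template), and `land_extent`.
#' @export
gen_regions <- function(scenario = synthetic_scenario()) {
  e <- scenario$extent; m <- scenario$land_margin
  le <- c(e[1] + m, e[2] - m, e[3] + m, e[4] - m)   # land extent
  midx <- (le[1] + le[2]) / 2; midy <- (le[3] + le[4]) / 2
  tdwg <- rect_regions(c("AAA", "AAB", "ABA", "ABB"),
                       xmin = c(le[1], midx, le[1], midx),
                       xmax = c(midx, le[2], midx, le[2]),
                       ymin = c(le[3], le[3], midy, midy),
                       ymax = c(midy, midy, le[4], le[4]))
  iso <- rect_regions("ZA", le[1], le[2], le[3], le[4])
  cs <- scenario$land_cellsize
  ncol <- round((e[2] - e[1]) / cs); nrow <- round((e[4] - e[3]) / cs)
  g <- clim_grid(matrix(NA_real_, nrow, ncol), e[1], e[3], cs)
  ctr <- cell_centers(g, rep(seq_len(nrow), each = ncol),
                      rep(seq_len(ncol), times = nrow))
  on_land <- ctr$lon > le[1] & ctr$lon < le[2] &
    ctr$lat > le[3] & ctr$lat < le[4]
  vals <- matrix(NA_real_, nrow, ncol)
  vals[cbind(rep(seq_len(nrow), each = ncol)[on_land],
             rep(seq_len(ncol), times = nrow)[on_land])] <- 1
  g$values <- vals
  list(tdwg = tdwg, iso = iso, land = g, land_extent = le)
}

benign_localities <- c("riverbank forest", "montane ridge",
                       "lowland rainforest", "steep slope above village",
                       "roadside near bridge", "dry creek bed")
cultivated_localities <- c("Botanical Garden, city center",
                           "Parque Nacional entrance, planted row",
                           "castel courtyard wall", "golf course margin",
                           "jardín municipal", "farm hedgerow")

rand_in_rect <- function(n, rect, margin = 0.2) {
  data.frame(lon = stats::runif(n, rect$xmin + margin, rect$xmax - margin),
             lat = stats::runif(n, rect$ymin + margin, rect$ymax - margin))
}

rect_of <- function(regions, code) {
  p <- regions[[match(code, region_codes(regions))]]
  r <- p$rings[[1]]
  list(xmin = min(r[, 1]), xmax = max(r[, 1]),
       ymin = min(r[, 2]), ymax = max(r[, 2]))
}

#' Synthetic multi-source occurrence table with planted defects
#'
#' Generates clean records uniformly inside each genus's native
#' botanical countries plus exactly the planted defect records of the
#' scenario, each tagged in a withheld truth table.  Replicates are
#' byte-identical in all nine replicate-key fields but attributed to a
#' second source; low-precision records carry one-decimal coordinate
#' text; coastal/offshore records sit west of the land edge within /
#' beyond 10 km of the nearest land-template cell center; cultivated
#' records carry a keyword locality; out-of-range records sit inside the
#' one botanical country excluded from their genus's native range.
#'
#' Coordinates are generated as text first and parsed from that text, so
#' the precision filter sees realistic textual forms.
#'
#' @param scenario a [synthetic_scenario()].
#' @param regions layers from [gen_regions()]; rebuilt when `NULL`.
#' @return list: `records` (occurrence data.frame), `truth` (data.frame
#'   `record_id`, `class` with classes `clean`, `duplicate`,
#'   `low_precision`, `coastal`, `offshore`, `cultivated`,
#'   `out_of_range`), `native` (named list genus -> native TDWG codes),
#'   `regions`.
#' @export
gen_occurrences <- function(scenario = synthetic_scenario(),
                            regions = NULL) {
  s <- scenario
  if (is.null(regions)) regions <- gen_regions(s)
  set.seed(s$seed)
  codes <- region_codes(regions$tdwg)
  genera <- paste0("Genus", LETTERS[seq_len(s$n_genera)])
  # each genus is native to all botanical countries but one
  forbidden <- codes[(seq_len(s$n_genera) - 1) %% length(codes) + 1]
  native <- stats::setNames(lapply(forbidden, function(f) setdiff(codes, f)),
                            genera)
  n_err <- s$n_duplicates + s$n_low_precision + s$n_coastal +
    s$n_offshore + s$n_cultivated + s$n_out_of_range
  n_clean <- s$n_records - n_err
  if (n_clean < s$n_genera)
    stop("scenario leaves fewer clean records than genera")

  rid <- 0L
  next_id <- function() {
    rid <<- rid + 1L
    sprintf("SYN-%05d", rid)
  }
  mk <- function(genus, lon_txt, lat_txt, locality, source) {
    data.frame(
      record_id = next_id(), genus = genus,
      species = paste(genus, sample(c("alpha", "beta", "gamma"), 1)),
      year = sample(1900:2020, 1),
      country_code_iso = NA_character_, country_code_tdwg = NA_character_,
      locality = locality, longitude_text = lon_txt,
      latitude_text = lat_txt,
      longitude = as.numeric(lon_txt), latitude = as.numeric(lat_txt),
      elevation = sample(0:3000, 1),
      catalog_number = sprintf("CAT%05d", rid),
      basis_of_record = sample(c("PRESERVED_SPECIMEN",
                                 "HUMAN_OBSERVATION"), 1),
      source = source, stringsAsFactors = FALSE)
  }
  genus_of <- function(i) genera[(i - 1) %% s$n_genera + 1]
  native_pt <- function(genus, digits = 4) {
    code <- sample(native[[genus]], 1)
    p <- rand_in_rect(1, rect_of(regions$tdwg, code))
    c(sprintf(paste0("%.", digits, "f"), p$lon),
      sprintf(paste0("%.", digits, "f"), p$lat))
  }

  rows <- list(); classes <- character(0)
  add <- function(rec, cls) {
    rows[[length(rows) + 1]] <<- rec
    classes <<- c(classes, cls)
  }

  for (i in seq_len(n_clean)) {
    g <- genus_of(i)
    pt <- native_pt(g)
    add(mk(g, pt[1], pt[2], sample(benign_localities, 1),
           sample(c("GBIF", "BIEN", "NBN"), 1)), "clean")
  }
  clean_idx <- seq_len(n_clean)

  # replicates: byte-identical key fields, different source label
  dup_of <- sample(clean_idx, s$n_duplicates,
                   replace = s$n_duplicates > n_clean)
  for (i in dup_of) {
    orig <- rows[[i]]
    rec <- orig
    rec$record_id <- next_id()
    rec$source <- if (orig$source == "GBIF") "BIEN" else "GBIF"
    add(rec, "duplicate")
  }

  for (i in seq_len(s$n_low_precision)) {
    g <- genus_of(i)
    pt <- native_pt(g, digits = 1)
    add(mk(g, pt[1], pt[2], sample(benign_localities, 1), "GBIF"),
        "low_precision")
  }

  le <- regions$land_extent
  west_lat <- function(g) {
    # a latitude whose west-edge land cell lies in a native country
    if ("AAA" %in% native[[g]])
      stats::runif(1, le[3] + 0.5, (le[3] + le[4]) / 2 - 0.5)
    else stats::runif(1, (le[3] + le[4]) / 2 + 0.5, le[4] - 0.5)
  }
  for (i in seq_len(s$n_coastal)) {
    g <- genus_of(i)
    lon <- le[1] - stats::runif(1, 0.01, 0.05)   # just offshore (< 10 km)
    add(mk(g, sprintf("%.4f", lon), sprintf("%.4f", west_lat(g)),
           sample(benign_localities, 1), "GBIF"), "coastal")
  }
  for (i in seq_len(s$n_offshore)) {
    g <- genus_of(i)
    lon <- le[1] - stats::runif(1, 0.5, 0.9)     # far offshore (> 10 km)
    add(mk(g, sprintf("%.4f", lon), sprintf("%.4f", west_lat(g)),
           sample(benign_localities, 1), "GBIF"), "offshore")
  }

  for (i in seq_len(s$n_cultivated)) {
    g <- genus_of(i)
    pt <- native_pt(g)
    add(mk(g, pt[1], pt[2], sample(cultivated_localities, 1), "GBIF"),
        "cultivated")
  }

  for (i in seq_len(s$n_out_of_range)) {
    g <- genus_of(i)
    p <- rand_in_rect(1, rect_of(regions$tdwg,
                                 setdiff(codes, native[[g]])[1]))
    add(mk(g, sprintf("%.4f", p$lon), sprintf("%.4f", p$lat),
           sample(benign_localities, 1), "GBIF"), "out_of_range")
  }

  records <- do.call(rbind, rows)
  truth <- data.frame(record_id = records$record_id, class = classes,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth, native = native,
       regions = regions)
}

#' Synthetic monthly mean-temperature grids
#'
#' Builds 12 co-registered grids with a linear latitudinal gradient and
#' a seasonal cycle: for month `m` and cell-center latitude `phi`,
#' `t = intercept - gradient * |phi| + seasonality * cos(2*pi*(m-7)/12) *
#' sign(phi)` plus optional seeded Gaussian noise.  With zero
#' seasonality and noise, biotemperature equals the clamped linear ramp,
#' so Holdridge zone boundaries sit at analytically known latitudes
#' `|phi| = (intercept - bound) / gradient`.
#'
#' @param def a [grid_def()].
#' @param intercept equatorial temperature, degC.
#' @param gradient cooling per degree of absolute latitude, degC/deg.
#' @param seasonality seasonal half-amplitude, degC (July-peaking in the
#'   northern hemisphere, inverted in the southern).
#' @param noise_sd standard deviation of per-cell-month noise, degC.
#' @param seed integer seed (used only for the noise).
#' @return a [monthly_temperature()].
#' @export
gen_monthly_climate <- function(def, intercept = 28, gradient = 0.35,
                                seasonality = 5, noise_sd = 0.1,
                                seed = 1) {
  set.seed(seed)
  lat <- def$ymin + (def$nrow - seq_len(def$nrow) + 0.5) * def$cellsize
  latm <- matrix(lat, def$nrow, def$ncol)
  hemi <- ifelse(latm >= 0, 1, -1)
  grids <- lapply(1:12, function(m) {
    t <- intercept - gradient * abs(latm) +
      seasonality * cos(2 * pi * (m - 7) / 12) * hemi
    if (noise_sd > 0)
      t <- t + matrix(stats::rnorm(length(latm), 0, noise_sd),
                      def$nrow, def$ncol)
    clim_grid(t, def$xmin, def$ymin, def$cellsize)
  })
  monthly_temperature(grids)
}
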