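#' Record-cleaning pipeline
#'
#' The cleaning stages implemented here target the two usual failure
#' modes of aggregated occurrence databases: redundancy (the same
#' specimen served by several source databases) and spatial noise
#' (truncated coordinates, points in the sea, cultivated individuals,
#' records outside the taxon's native range).  Stages run in a fixed
#' order: administrative harmonization, replicate removal,
#' coordinate-precision filter, land/coastal filter, cultivated-record
#' handling, native-range filter.  Every stage conserves records:
#' input = kept + removed.
#'
#' @name cleaning
NULL

norm_txt <- function(x) {
  x[is.na(x)] <- ""
  tolower(trimws(x))
}

#' Remove replicate records
#'
#' Records are replicates when they agree on the normalized combination
#' of the nine voucher fields: species name, collection year, country
#' code (TDWG), locality, longitude, latitude (both compared as text),
#' elevation, catalog number, and basis of record.  The `source` label is
#' deliberately not part of the key — replicates are typically the same
#' specimen served by two databases.  The first record in stable input
#' order is kept.
#'
#' @param records occurrence data.frame.
#' @return list with `kept`, `removed`, `n_removed`.
#' @export
deduplicate <- function(records) {
  key <- paste(norm_txt(records$species), norm_txt(records$year),
               norm_txt(records$country_code_tdwg),
               norm_txt(records$locality),
               norm_txt(records$longitude_text),
               norm_txt(records$latitude_text),
               norm_txt(records$elevation),
               norm_txt(records$catalog_number),
               norm_txt(records$basis_of_record), sep = "\r")
  dup <- duplicated(key)
  list(kept = records[!dup, , drop = FALSE],
       removed = records[dup, , drop = FALSE],
       n_removed = sum(dup))
}

n_decimals <- function(txt) {
  # digits after the decimal point of the *textual* coordinate; trailing
  # zeros count ("12.30" has 2), absent point counts 0
  txt <- trimws(txt)
  has <- grepl(".", txt, fixed = TRUE)
  out <- integer(length(txt))
  out[has] <- nchar(sub("^[^.]*\\.", "", txt[has]))
  out
}

#' Coordinate-precision filter
#'
#' Drops records whose textual longitude or latitude has fewer than two
#' digits after the decimal separator.  A coordinate written `"12.3"`
#' carries about 11 km of positional slack at the equator — too coarse
#' for climatic assignment — while `"12.30"` asserts two decimals and is
#' kept.  The rule inspects the original text, not the parsed number
#' (numerically, 12.3 and 12.30 are indistinguishable).
#'
#' @param records occurrence data.frame.
#' @param min_decimals minimum decimals required on both coordinates.
#' @return list with `kept`, `removed`, `n_removed`.
#' @export
filter_coordinate_precision <- function(records, min_decimals = 2L) {
  ok <- n_decimals(records$longitude_text) >= min_decimals &
    n_decimals(records$latitude_text) >= min_decimals
  list(kept = records[ok, , drop = FALSE],
       removed = records[!ok, , drop = FALSE],
       n_removed = sum(!ok))
}

#' Land / coastal-distance filter
#'
#' Classifies records against a land template grid (a grid whose data
#' cells define the land surface, e.g. an annual-mean-temperature
#' layer).  Records inside a data cell pass unchanged.  Records off land
#' but within `threshold_km` (great-circle distance) of the nearest data
#' cell's center are treated as misplaced coastal records: they are kept
#' and their coordinates are snapped to that nearest cell center, so that
#' seaboard environments are not lost.  Records farther than
#' `threshold_km` from any data cell are removed as erroneous.
#'
#' @param records occurrence data.frame.
#' @param land a [clim_grid()] whose non-`NA` cells are land.
#' @param threshold_km coastal distance threshold (default 10 km).
#' @return list with `on_land`, `snapped` (coordinates replaced, column
#'   `snapped = TRUE`), `removed`, `kept` (on_land + snapped, original
#'   order), and counts `n_snapped`, `n_removed`.
#' @export
classify_by_land_distance <- function(records, land, threshold_km = 10) {
  stopifnot(inherits(land, "clim_grid"))
  if (!any(!is.na(land$values))) stop("land template has no data cells")
  v <- grid_extract(land, records$longitude, records$latitude)
  on_land <- !is.na(v)
  off <- which(!on_land)
  snapped_idx <- integer(0)
  snap_to <- matrix(numeric(0), 0, 2)
  if (length(off)) {
    land_idx <- which(!is.na(land$values), arr.ind = TRUE)
    ctr <- cell_centers(land, land_idx[, 1], land_idx[, 2])
    for (i in off) {
      p <- c(records$longitude[i], records$latitude[i])
      # candidate data cells within a generous lon/lat window
      lat_m <- threshold_km / 110 + land$cellsize
      lon_m <- threshold_km / (111 * max(cos(p[2] * pi / 180), 0.05)) +
        land$cellsize
      cand <- which(abs(ctr$lat - p[2]) <= lat_m &
                      abs(ctr$lon - p[1]) <= lon_m)
      if (!length(cand)) next
      d <- geosphere::distGeo(p, cbind(ctr$lon[cand], ctr$lat[cand])) / 1000
      j <- cand[which.min(d)]
      if (min(d) <= threshold_km) {
        snapped_idx <- c(snapped_idx, i)
        snap_to <- rbind(snap_to, c(ctr$lon[j], ctr$lat[j]))
      }
    }
  }
  removed_idx <- setdiff(off, snapped_idx)
  records$snapped <- FALSE
  if (length(snapped_idx)) {
    records$longitude[snapped_idx] <- snap_to[, 1]
    records$latitude[snapped_idx] <- snap_to[, 2]
    records$longitude_text[snapped_idx] <- sprintf("%.6f", snap_to[, 1])
    records$latitude_text[snapped_idx] <- sprintf("%.6f", snap_to[, 2])
    records$snapped[snapped_idx] <- TRUE
  }
  keep_idx <- sort(c(which(on_land), snapped_idx))
  list(on_land = records[on_land, , drop = FALSE],
       snapped = records[snapped_idx, , drop = FALSE],
       removed = records[removed_idx, , drop = FALSE],
       kept = records[keep_idx, , drop = FALSE],
       n_snapped = length(snapped_idx),
       n_removed = length(removed_idx))
}

#' Default cultivated-locality keyword list
#'
#' Twelve multilingual keywords indicating planted or managed
#' individuals: cultivated, cultivado, park, parque, garden, jardín,
#' castel, castillo, golf, cementerio, zoo, farm.
#'
#' @export
cultivated_keywords <- function() {
  c("cultivated", "cultivado", "park", "parque", "garden",
    "jardín", "castel", "castillo", "golf", "cementerio",
    "zoo", "farm")
}

fold_chr <- function(x) {
  # diacritic folding: transliterate to ASCII, then drop the accent
  # residue some iconv implementations leave ("jardín" -> "jard'in")
  out <- iconv(x, from = "UTF-8", to = "ASCII//TRANSLIT")
  out[is.na(out)] <- x[is.na(out)]
  tolower(gsub("[^[:alnum:] ]", "", out))
}

#' Flag probably-cultivated records by locality keywords
#'
#' A record is flagged when its locality contains any keyword as a
#' case-insensitive, diacritic-insensitive substring ("jardin" matches
#' "Jardín").  Flagging and removal are separate steps: the keyword list
#' produces false positives by design (e.g. native stands inside
#' national *park*s), so flagged records are returned for review and
#' removal is a configurable decision of [run_cleaning()].
#'
#' @param records occurrence data.frame.
#' @param keywords keyword list; defaults to [cultivated_keywords()].
#' @return list with `flagged`, `unflagged`, `n_flagged`.
#' @export
flag_cultivated <- function(records, keywords = cultivated_keywords()) {
  loc <- fold_chr(ifelse(is.na(records$locality), "", records$locality))
  kw <- fold_chr(keywords)
  hit <- rep(FALSE, nrow(records))
  for (k in kw) hit <- hit | grepl(k, loc, fixed = TRUE)
  list(flagged = records[hit, , drop = FALSE],
       unflagged = records[!hit, , drop = FALSE],
       n_flagged = sum(hit))
}

#' Native-range filter
#'
#' Keeps a record only when its TDWG level-3 code belongs to the native
#' range declared for its genus.  Records with a missing TDWG code
#' cannot match and are removed (counted separately).
#'
#' @param records occurrence data.frame with `country_code_tdwg` filled.
#' @param native named list: genus -> character vector of TDWG level-3
#'   codes.  Every genus present in `records` must appear.
#' @return list with `kept`, `removed`, `n_removed`,
#'   `n_missing_code` (subset of `n_removed`).
#' @export
filter_native_range <- function(records, native) {
  gen <- unique(records$genus)
  missing <- setdiff(gen, names(native))
  if (length(missing))
    stop("genera absent from the native-range map: ",
         paste(missing, collapse = ", "))
  bad <- vapply(native, function(v) length(v) == 0 || any(is.na(v)) ||
                  any(v != toupper(v)), logical(1))
  if (any(bad))
    stop("native-range codes must be non-empty uppercase strings")
  code <- records$country_code_tdwg
  ok <- !is.na(code) & mapply(function(g, cc) cc %in% native[[g]],
                              records$genus, code, USE.NAMES = FALSE)
  ok <- as.logical(ok)
  list(kept = records[ok, , drop = FALSE],
       removed = records[!ok, , drop = FALSE],
       n_removed = sum(!ok),
       n_missing_code = sum(is.na(code)))
}

#' Percentage of records lost in cleaning
#'
#' `100 * (input - kept) / input`, rounded to two decimals.
#'
#' @param input,kept record counts before and after cleaning.
#' @export
loss_percent <- function(input, kept) {
  round(100 * (input - kept) / input, 2)
}

#' Representation of a genus in the cleaned database
#'
#' `100 * n_genus / n_total`, rounded to two decimals: the share of the
#' database's records belonging to one genus.
#'
#' @param n_genus records of the genus after cleaning.
#' @param n_total total records in the cleaned database.
#' @export
representation_percent <- function(n_genus, n_total) {
  round(100 * n_genus / n_total, 2)
}

#' Run the full cleaning pipeline
#'
#' Applies the stages in fixed order — harmonize, deduplicate,
#' precision filter, land/coastal filter, cultivated handling,
#' native-range filter — and accounts for every record.  Snapped coastal
#' records acquire new coordinates, so when polygon layers are supplied
#' they are re-harmonized after the coastal stage (otherwise a record
#' snapped inland would still carry its offshore, code-less lookup).
#'
#' @param records occurrence data.frame (as from [read_occurrences()]).
#' @param config list with optional components:
#'   `tdwg_regions`, `iso_regions` ([region_set()]s; enables the
#'   harmonize stage), `land` (a [clim_grid()]; enables the land stage),
#'   `threshold_km` (default 10), `keywords` (default
#'   [cultivated_keywords()]), `remove_cultivated` (default `TRUE`;
#'   `FALSE` keeps flagged records but still reports them),
#'   `native` (named list; enables the native-range stage),
#'   `min_decimals` (default 2).
#' @return list with `records` (the cleaned table), `report` (a
#'   `cleaning_report`), and `removed` (per-stage data.frames of the
#'   records each stage removed, for audit).
#' @export
run_cleaning <- function(records, config = list()) {
  cfg <- utils::modifyList(
    list(tdwg_regions = NULL, iso_regions = NULL, land = NULL,
         threshold_km = 10, keywords = cultivated_keywords(),
         remove_cultivated = TRUE, native = NULL, min_decimals = 2L),
    config)
  n_in <- nrow(records)
  stages <- data.frame(stage = character(0), input = integer(0),
                       removed = integer(0), snapped = integer(0),
                       kept = integer(0))
  removed <- list()
  per_genus_input <- table(records$genus)
  add_stage <- function(name, input, rem, snap, kept) {
    stages <<- rbind(stages, data.frame(stage = name, input = input,
                                        removed = rem, snapped = snap,
                                        kept = kept))
  }

  if (!is.null(cfg$tdwg_regions)) {
    records <- harmonize_country_codes(records, cfg$tdwg_regions,
                                       cfg$iso_regions)
    add_stage("harmonize", n_in, 0L, 0L, n_in)
  }

  dd <- deduplicate(records)
  add_stage("deduplicate", nrow(records), dd$n_removed, 0L, nrow(dd$kept))
  removed$deduplicate <- dd$removed
  records <- dd$kept

  pr <- filter_coordinate_precision(records, cfg$min_decimals)
  add_stage("precision", nrow(records) , pr$n_removed, 0L, nrow(pr$kept))
  removed$precision <- pr$removed
  records <- pr$kept

  if (!is.null(cfg$land)) {
    ld <- classify_by_land_distance(records, cfg$land, cfg$threshold_km)
    add_stage("land", nrow(records), ld$n_removed, ld$n_snapped,
              nrow(ld$kept))
    removed$land <- ld$removed
    records <- ld$kept
    if (!is.null(cfg$tdwg_regions) && ld$n_snapped > 0) {
      snapped_rows <- which(records$snapped)
      reh <- harmonize_country_codes(records[snapped_rows, , drop = FALSE],
                                     cfg$tdwg_regions, cfg$iso_regions)
      records[snapped_rows, names(reh)] <- reh
    }
  }

  fc <- flag_cultivated(records, cfg$keywords)
  if (isTRUE(cfg$remove_cultivated)) {
    add_stage("cultivated", nrow(records), fc$n_flagged, 0L,
              nrow(fc$unflagged))
    removed$cultivated <- fc$flagged
    records <- fc$unflagged
  } else {
    add_stage("cultivated", nrow(records), 0L, 0L, nrow(records))
    records$cultivated_flag <- records$record_id %in% fc$flagged$record_id
  }

  if (!is.null(cfg$native)) {
    nr <- filter_native_range(records, cfg$native)
    add_stage("native_range", nrow(records), nr$n_removed, 0L,
              nrow(nr$kept))
    removed$native_range <- nr$removed
    records <- nr$kept
  }

  kept_tab <- table(factor(records$genus, levels = names(per_genus_input)))
  per_genus <- data.frame(
    genus = names(per_genus_input),
    input = as.integer(per_genus_input),
    kept = as.integer(kept_tab),
    stringsAsFactors = FALSE)
  per_genus$loss_percent <- loss_percent(per_genus$input, per_genus$kept)

  report <- structure(list(
    n_input = n_in, n_kept = nrow(records),
    loss_percent = loss_percent(n_in, nrow(records)),
    stages = stages, per_genus = per_genus), class = "cleaning_report")
  list(records = records, report = report, removed = removed)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report> %d -> %d records (loss %.2f%%)\n",
              x$n_input, x$n_kept, x$loss_percent))
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Write a cleaning report
#'
#' @param report a `cleaning_report` from [run_cleaning()].
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @export
write_cleaning_report <- function(report, json_path = NULL,
                                  csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(unclass(report), json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  if (!is.null(csv_path))
    utils::write.csv(report$stages, csv_path, row.names = FALSE)
  invisible(report)
}
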