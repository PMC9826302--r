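#' Occurrence tables
#'
#' Occurrence records travel through the pipeline as a plain data.frame
#' with one row per record and a fixed set of columns (Darwin-Core-style
#' content, standardized names):
#'
#' * `record_id` — opaque unique identifier
#' * `genus`, `species` — taxon names (`species` is the binomial)
#' * `year` — collection year (integer, may be `NA`)
#' * `country_code_iso`, `country_code_tdwg` — ISO-3166-1 alpha-2 and
#'   TDWG level-3 codes (may be `NA`)
#' * `locality` — free-text locality
#' * `longitude_text`, `latitude_text` — the *original textual*
#'   coordinate representation (the coordinate-precision filter is only
#'   well defined on text: `"12.30"` has two decimals, `12.3` has not)
#' * `longitude`, `latitude` — parsed decimal degrees WGS84
#' * `elevation` — meters (may be `NA`)
#' * `catalog_number`, `basis_of_record` — voucher fields
#' * `source` — origin-database label
#'
#' @name occurrence-table
NULL

occ_columns <- c("record_id", "genus", "species", "year",
                 "country_code_iso", "country_code_tdwg", "locality",
                 "longitude_text", "latitude_text", "longitude", "latitude",
                 "elevation", "catalog_number", "basis_of_record", "source")

#' Default column mapping for reading occurrence files
#'
#' Maps the standardized field names to Darwin-Core column headers.
#' Override entries to read files with different headers; set an entry to
#' `NA` to skip an optional field.
#'
#' @export
default_column_map <- function() {
  c(genus = "genus", species = "species", year = "year",
    country_code_iso = "countryCode", country_code_tdwg = "countryCodeTDWG",
    locality = "locality", longitude = "decimalLongitude",
    latitude = "decimalLatitude", elevation = "elevation",
    catalog_number = "catalogNumber", basis_of_record = "basisOfRecord")
}

#' Read an occurrence table
#'
#' Reads a delimited text file into the standard occurrence data.frame
#' (see [occurrence-table]).  Coordinates are kept verbatim as text and
#' parsed to decimal degrees; rows whose coordinates do not parse or fall
#' outside valid WGS84 bounds are rejected and counted, never silently
#' dropped.
#'
#' @param path delimited text file with a header row.
#' @param source_label origin-database label stored in `source`.
#' @param column_map named character vector mapping standard field names
#'   to file column headers; see [default_column_map()].
#' @param sep field separator (`","` or `"\t"`).
#' @return list with `records` (the accepted rows), `n_rejected`, and
#'   `rejected` (the offending raw rows).
#' @export
read_occurrences <- function(path, source_label,
                             column_map = default_column_map(),
                             sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           fileEncoding = "UTF-8")
  for (f in c("genus", "longitude", "latitude")) {
    col <- column_map[[f]]
    if (is.null(col) || is.na(col) || !col %in% names(raw))
      stop("column_map: mandatory field '", f,
           "' not found in file columns")
  }
  pick <- function(f) {
    col <- column_map[[f]]
    if (is.null(col) || is.na(col) || !col %in% names(raw))
      rep(NA_character_, nrow(raw))
    else raw[[col]]
  }
  lon_txt <- trimws(pick("longitude"))
  lat_txt <- trimws(pick("latitude"))
  lon <- suppressWarnings(as.numeric(lon_txt))
  lat <- suppressWarnings(as.numeric(lat_txt))
  ok <- !is.na(lon) & !is.na(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  records <- data.frame(
    record_id = paste0(source_label, "-", seq_len(nrow(raw))),
    genus = trimws(pick("genus")),
    species = trimws(pick("species")),
    year = suppressWarnings(as.integer(pick("year"))),
    country_code_iso = pick("country_code_iso"),
    country_code_tdwg = pick("country_code_tdwg"),
    locality = pick("locality"),
    longitude_text = lon_txt, latitude_text = lat_txt,
    longitude = lon, latitude = lat,
    elevation = suppressWarnings(as.numeric(pick("elevation"))),
    catalog_number = pick("catalog_number"),
    basis_of_record = pick("basis_of_record"),
    source = source_label,
    stringsAsFactors = FALSE
  )
  list(records = records[ok, , drop = FALSE],
       n_rejected = sum(!ok),
       rejected = raw[!ok, , drop = FALSE])
}

#' Write an occurrence table
#'
#' Writes the standard occurrence data.frame as CSV.  Textual coordinate
#' columns are written verbatim so that a read/write/read cycle is the
#' identity.
#'
#' @param records occurrence data.frame.
#' @param path output CSV path.
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Re-read an occurrence table written by [write_occurrences()]
#'
#' @param path CSV written by [write_occurrences()].
#' @export
read_occurrences_std <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", na.strings = "",
                         check.names = FALSE, fileEncoding = "UTF-8")
  raw$year <- suppressWarnings(as.integer(raw$year))
  raw$longitude <- as.numeric(raw$longitude)
  raw$latitude <- as.numeric(raw$latitude)
  raw$elevation <- suppressWarnings(as.numeric(raw$elevation))
  raw[occ_columns]
}

#' Harmonize administrative codes by spatial lookup
#'
#' Replaces the TDWG level-3 and ISO country codes of every record with
#' the code of the polygon containing its coordinates.  Existing codes
#' are overwritten, which also repairs typographic errors in the source
#' data.  Points contained in no polygon get a missing code and are
#' flagged in the logical column `no_polygon`.
#'
#' The operation is idempotent: a second application is a no-op.
#'
#' @param records occurrence data.frame with valid coordinates.
#' @param tdwg_regions [region_set()] of TDWG level-3 botanical countries.
#' @param iso_regions optional [region_set()] of ISO countries.
#' @return records with `country_code_tdwg`, `country_code_iso` and
#'   `no_polygon` updated.
#' @export
harmonize_country_codes <- function(records, tdwg_regions,
                                    iso_regions = NULL) {
  stopifnot(inherits(tdwg_regions, "region_set"))
  records$country_code_tdwg <-
    locate_regions(tdwg_regions, records$longitude, records$latitude)
  if (!is.null(iso_regions))
    records$country_code_iso <-
      locate_regions(iso_regions, records$longitude, records$latitude)
  records$no_polygon <- is.na(records$country_code_tdwg)
  records
}

#' Rewrite taxon names through a synonym table
#'
#' Applies an old-binomial to accepted-name mapping (used for genera
#' whose records were published under earlier generic circumscriptions).
#' Unmatched names are untouched; an empty table is a no-op.
#'
#' @param records occurrence data.frame.
#' @param synonyms data.frame with columns `old_name` (binomial as found
#'   in the sources), `genus`, `species` (accepted name).
#' @return list with `records` and `n_rewritten`.
#' @export
apply_synonym_table <- function(records, synonyms) {
  if (is.null(synonyms) || nrow(synonyms) == 0)
    return(list(records = records, n_rewritten = 0L))
  stopifnot(all(c("old_name", "genus", "species") %in% names(synonyms)))
  key <- trimws(records$species)
  hit <- match(key, trimws(synonyms$old_name))
  n <- sum(!is.na(hit))
  idx <- which(!is.na(hit))
  records$genus[idx] <- synonyms$genus[hit[idx]]
  records$species[idx] <- synonyms$species[hit[idx]]
  list(records = records, n_rewritten = n)
}
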