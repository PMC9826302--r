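#' Default pipeline configuration
#'
#' Returns the full configuration tree used by [run_pipeline()];
#' user-supplied YAML files (or override lists) are merged over it, so a
#' config file only needs the entries it changes.
#'
#' @export
default_config <- function() {
  list(
    seed = 1,
    scenario = list(n_genera = 5, n_records = 100, n_duplicates = 10,
                    n_low_precision = 5, n_coastal = 4, n_offshore = 3,
                    n_cultivated = 2, n_out_of_range = 4),
    climate = list(cellsize = 0.25, intercept = 28, gradient = 0.35,
                   seasonality = 5, noise_sd = 0.1),
    cleaning = list(threshold_km = 10, remove_cultivated = TRUE,
                    min_decimals = 2),
    classification = "latitudinal",
    profile = list(threshold = 0.75, oversample_cap = 1500,
                   target = 1000),
    sampling = list(cell_size = 1, k = 5, hotspot_frac = 0.25,
                    start_year = 1900)
  )
}

load_config <- function(config = NULL, overrides = list()) {
  cfg <- default_config()
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.list(config)) cfg <- utils::modifyList(cfg, config)
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

log_info <- function(...) message(sprintf("[occuclim] %s", sprintf(...)))

pipe_path <- function(out_dir, name) file.path(out_dir, name)

need_file <- function(path, producer) {
  if (!file.exists(path))
    stop("missing input '", path, "' — run the '", producer,
         "' step first")
  path
}

#' Run the analysis pipeline
#'
#' Orchestrates the package end to end on disk artifacts.  Subcommands:
#'
#' * `simulate` — generate the synthetic scenario (occurrences, truth
#'   table, region layers, land mask, monthly climate grids)
#' * `clean` — run the cleaning pipeline on the occurrence table
#' * `build-layers` — build the latitudinal and Holdridge
#'   regionalizations of the study grid
#' * `classify` — assign cleaned records to the categories of the
#'   configured classification
#' * `profile` — per-genus and clade-level climatic profiles
#' * `range-metrics` — AOO/EOO and size class per genus
#' * `sampling` — sampling-effort grid, Jenks classes, hotspot flags,
#'   temporal series, richness per botanical country
#' * `all` — all of the above in order
#'
#' Every run ends by writing `manifest.json` (inputs, config, seed, MD5
#' checksums of all artifacts).  Outputs are deterministic given
#' (config, seed).
#'
#' @param command subcommand, see above.
#' @param config path to a YAML config file, or a config list; merged
#'   over [default_config()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; overrides the config seed.
#' @param overrides named list merged over the config (deepest wins).
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(command = "all", config = NULL,
                         out_dir = "occuclim-out", seed = NULL,
                         overrides = list()) {
  commands <- c("simulate", "clean", "build-layers", "classify",
                "profile", "range-metrics", "sampling", "all")
  if (!command %in% commands)
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "))
  cfg <- load_config(config, overrides)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  steps <- if (command == "all")
    c("simulate", "clean", "build-layers", "classify", "profile",
      "range-metrics", "sampling")
  else command
  for (st in steps) do.call(paste0("step_", gsub("-", "_", st)),
                            list(cfg, out_dir))
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.json")
  manifest <- list(
    command = command, seed = cfg$seed,
    config_hash = substr(tools::md5sum(
      textConnection_md5(yaml::as.yaml(cfg))), 1, 32),
    config = cfg,
    artifacts = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, pipe_path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_info("wrote manifest with %d artifacts to %s", length(files),
           out_dir)
  invisible(manifest)
}

textConnection_md5 <- function(txt) {
  tmp <- tempfile()
  writeLines(txt, tmp)
  tmp
}

scenario_from_cfg <- function(cfg) {
  do.call(synthetic_scenario, c(list(seed = cfg$seed), cfg$scenario))
}

step_simulate <- function(cfg, out_dir) {
  s <- scenario_from_cfg(cfg)
  sim <- gen_occurrences(s)
  write_occurrences(sim$records, pipe_path(out_dir, "occurrences.csv"))
  utils::write.csv(sim$truth, pipe_path(out_dir, "truth.csv"),
                   row.names = FALSE)
  write_geojson_regions(sim$regions$tdwg, pipe_path(out_dir, "tdwg.geojson"))
  write_geojson_regions(sim$regions$iso, pipe_path(out_dir, "iso.geojson"))
  write_ascii_grid(sim$regions$land, pipe_path(out_dir, "land.asc"))
  jsonlite::write_json(sim$native, pipe_path(out_dir, "native.json"))
  log_info("simulate: %d records (%d planted defects) for %d genera",
           nrow(sim$records),
           sum(sim$truth$class != "clean"), s$n_genera)
  invisible(sim)
}

step_clean <- function(cfg, out_dir) {
  records <- read_occurrences_std(
    need_file(pipe_path(out_dir, "occurrences.csv"), "simulate"))
  tdwg <- read_geojson_regions(pipe_path(out_dir, "tdwg.geojson"))
  iso <- read_geojson_regions(pipe_path(out_dir, "iso.geojson"))
  land <- read_ascii_grid(pipe_path(out_dir, "land.asc"))
  native <- lapply(jsonlite::read_json(pipe_path(out_dir, "native.json")),
                   function(x) unlist(x))
  res <- run_cleaning(records, c(
    list(tdwg_regions = tdwg, iso_regions = iso, land = land,
         native = native), cfg$cleaning))
  write_occurrences(res$records, pipe_path(out_dir, "cleaned.csv"))
  write_cleaning_report(res$report,
                        json_path = pipe_path(out_dir, "cleaning_report.json"),
                        csv_path = pipe_path(out_dir, "cleaning_stages.csv"))
  for (nm in names(res$removed))
    if (nrow(res$removed[[nm]]))
      utils::write.csv(res$removed[[nm]],
                       pipe_path(out_dir, paste0("removed_", nm, ".csv")),
                       row.names = FALSE)
  for (i in seq_len(nrow(res$report$stages)))
    with(res$report$stages[i, ],
         log_info("clean/%s: input %d removed %d snapped %d kept %d",
                  stage, input, removed, snapped, kept))
  invisible(res)
}

study_grid_def <- function(cfg) {
  s <- scenario_from_cfg(cfg)
  e <- s$extent
  cs <- cfg$climate$cellsize
  grid_def(e[1], e[3], round((e[2] - e[1]) / cs),
           round((e[4] - e[3]) / cs), cs)
}

step_build_layers <- function(cfg, out_dir) {
  def <- study_grid_def(cfg)
  lat_layer <- build_latitudinal_raster(def)
  monthly <- gen_monthly_climate(def, intercept = cfg$climate$intercept,
                                 gradient = cfg$climate$gradient,
                                 seasonality = cfg$climate$seasonality,
                                 noise_sd = cfg$climate$noise_sd,
                                 seed = cfg$seed)
  hold_layer <- build_holdridge_raster(monthly)
  write_regionalization(lat_layer, pipe_path(out_dir, "latitudinal.asc"))
  write_regionalization(hold_layer, pipe_path(out_dir, "holdridge.asc"))
  log_info("build-layers: %s (%d categories), %s (%d categories)",
           lat_layer$name, length(unique(stats::na.omit(
             as.vector(lat_layer$grid$values)))),
           hold_layer$name, length(unique(stats::na.omit(
             as.vector(hold_layer$grid$values)))))
  invisible(list(latitudinal = lat_layer, holdridge = hold_layer))
}

active_layer <- function(cfg, out_dir) {
  name <- cfg$classification
  path <- pipe_path(out_dir, paste0(name, ".asc"))
  read_regionalization(need_file(path, "build-layers"))
}

step_classify <- function(cfg, out_dir) {
  records <- read_occurrences_std(
    need_file(pipe_path(out_dir, "cleaned.csv"), "clean"))
  layer <- active_layer(cfg, out_dir)
  cat_ <- sample_regionalization(records$longitude, records$latitude,
                                 layer)
  out <- data.frame(record_id = records$record_id, genus = records$genus,
                    category = as.vector(cat_))
  utils::write.csv(out, pipe_path(out_dir, "classified.csv"),
                   row.names = FALSE)
  log_info("classify: %d records against '%s' (%d unclassified)",
           nrow(out), layer$name, attr(cat_, "n_unclassified"))
  invisible(out)
}

#' Qualitative tropical/temperate labels for a set of records
#'
#' Derives a label per genus from the latitudinal zonation of its
#' records' absolute latitudes: tropical when the majority of records
#' sit equatorward of 23.5 degrees, temperate otherwise.  Used by the
#' pipeline when no label map is supplied.
#'
#' @param records occurrence data.frame.
#' @return named character vector genus -> label.
#' @export
derive_qualitative_labels <- function(records) {
  vapply(split(records, records$genus), function(df) {
    if (mean(abs(df$latitude) < 23.5) >= 0.5) "tropical" else "temperate"
  }, character(1))
}

step_profile <- function(cfg, out_dir) {
  records <- read_occurrences_std(
    need_file(pipe_path(out_dir, "cleaned.csv"), "clean"))
  layer <- active_layer(cfg, out_dir)
  prof <- list()
  for (df in split(records, records$genus)) {
    p <- try(genus_profile(df, layer, threshold = cfg$profile$threshold),
             silent = TRUE)
    if (inherits(p, "try-error")) {
      log_info("profile: skipping genus %s (%s)", df$genus[1],
               trimws(attr(p, "condition")$message))
    } else prof[[length(prof) + 1]] <- p
  }
  prof[[length(prof) + 1]] <-
    clade_profile(records, layer,
                  oversample_cap = cfg$profile$oversample_cap,
                  target = cfg$profile$target, seed = cfg$seed,
                  threshold = cfg$profile$threshold)
  tab <- profiles_to_table(prof, pipe_path(out_dir, "profiles.csv"))
  jsonlite::write_json(
    lapply(prof, function(p) list(taxon = p$taxon,
                                  assignment = p$assignment,
                                  n_used = p$n_used)),
    pipe_path(out_dir, "profiles_summary.json"), auto_unbox = TRUE,
    digits = NA)
  log_info("profile: %d profiles on '%s'", length(prof), layer$name)
  invisible(tab)
}

step_range_metrics <- function(cfg, out_dir) {
  records <- read_occurrences_std(
    need_file(pipe_path(out_dir, "cleaned.csv"), "clean"))
  rm_ <- range_metrics(records)
  utils::write.csv(rm_, pipe_path(out_dir, "range_metrics.csv"),
                   row.names = FALSE)
  log_info("range-metrics: %d genera (%d restricted, %d widespread)",
           nrow(rm_), sum(rm_$size_class == "restricted"),
           sum(rm_$size_class == "widespread"))
  invisible(rm_)
}

step_sampling <- function(cfg, out_dir) {
  records <- read_occurrences_std(
    need_file(pipe_path(out_dir, "cleaned.csv"), "clean"))
  gc_ <- grid_counts(records, cell_size = cfg$sampling$cell_size)
  nz <- gc_$grid$values[gc_$grid$values > 0]
  k <- min(cfg$sampling$k, length(unique(nz)))
  jb <- jenks_breaks(nz, k)
  hs <- hotspot_categories(gc_, jb, frac = cfg$sampling$hotspot_frac)
  write_ascii_grid(gc_$grid, pipe_path(out_dir, "effort.asc"))
  utils::write.csv(hs$classes, pipe_path(out_dir, "effort_classes.csv"),
                   row.names = FALSE)
  labels <- derive_qualitative_labels(records)
  tdwg <- read_geojson_regions(pipe_path(out_dir, "tdwg.geojson"))
  ts_ <- temporal_series(records, tdwg, labels,
                         start_year = cfg$sampling$start_year)
  utils::write.csv(ts_$series, pipe_path(out_dir, "temporal_series.csv"),
                   row.names = FALSE)
  utils::write.csv(ts_$quantile_years,
                   pipe_path(out_dir, "temporal_quantiles.csv"),
                   row.names = FALSE)
  rich <- richness_by_unit(records, tdwg, labels)
  utils::write.csv(rich, pipe_path(out_dir, "richness.csv"),
                   row.names = FALSE)
  log_info("sampling: max %g records/cell, hotspot threshold %d, %d hotspot classes",
           hs$max_count, hs$threshold_records, sum(hs$classes$hotspot))
  invisible(list(grid = gc_, jenks = jb, hotspots = hs, temporal = ts_,
                 richness = rich))
}
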