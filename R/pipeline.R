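#' Load and resolve a run configuration
#'
#' A run is described by a single YAML file (or equivalent list). Recognized
#' fields, with defaults in parentheses:
#' `seed` (1), `out` (`"hotspotr_out"`), `tracks` (path, required),
#' `tracks_column_map` (optional named map), `landcover` (GeoJSON path,
#' required), `perches` (optional GeoJSON path), `bbox` (optional; inferred
#' from the landcover polygon extent, else from the tracks), `cell_size`
#' (50), `resample` (`interval_min` 15, `tolerance_min` 2), `season`
#' (`label`, `start`, `end`, `timezone`), `criteria` (see
#' [hotspot_criteria()]), `surveys` (named paths per taxon group),
#' `standardize` (TRUE), `persistence` (`designation_year` plus a list of
#' `seasons`, each with `year`, `start`, `end`).
#'
#' @param config path to a YAML file, or a list with the fields above.
#' @return resolved configuration list.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(seed = 1, out = "hotspotr_out", cell_size = 50,
                   standardize = TRUE,
                   resample = list(interval_min = 15, tolerance_min = 2),
                   criteria = list())
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("tracks", "landcover")) {
    if (is.null(config[[nm]])) stop("config is missing required field: ", nm)
    if (!file.exists(config[[nm]])) {
      stop("config stage '", nm, "': file not found: ", config[[nm]])
    }
  }
  if (is.null(config$season)) stop("config is missing required field: season")
  config
}

config_season <- function(s) {
  season_window(s$label %||% "season", s$start, s$end, s$timezone %||% "UTC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_criteria <- function(cl) {
  do.call(hotspot_criteria, cl)
}

#' Run the designation stage end-to-end
#'
#' read tracks -> thin to the common interval -> restrict to the season ->
#' build the grid and landcover mask -> tally per-cell usage -> designate
#' hotspot/control pairs. All intermediates are written under `config$out`
#' and stage-by-stage record counts are logged.
#'
#' @param config a [run_config()] (or path / list accepted by it).
#' @return the [designate_sites()] result, invisibly; side effects:
#'   `usage.csv`, `sites.csv`, `sites.geojson`, `rejected.csv`,
#'   `unpaired.csv`, `resolved_config.yaml` in the output directory.
#' @export
run_designation <- function(config) {
  config <- run_config(config)
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  tracks <- read_tracks(config$tracks, column_map = config$tracks_column_map)
  message("stage tracks: ", nrow(tracks), " fixes, ",
          length(unique(tracks$individual_id)), " individuals")

  polygons <- geojson_read_polygons(config$landcover)
  perches <- if (!is.null(config$perches) && file.exists(config$perches)) {
    geojson_read_points(config$perches)
  } else NULL

  bbox <- config$bbox
  if (is.null(bbox)) {
    bbox <- if (nrow(polygons) > 0) {
      c(min(polygons$x), min(polygons$y), max(polygons$x), max(polygons$y))
    } else {
      c(min(tracks$x), min(tracks$y),
        max(tracks$x) + 1e-6, max(tracks$y) + 1e-6)
    }
  }
  grid <- build_grid(bbox, config$cell_size)
  mask <- rasterize_landcover(grid, polygons, perches)
  message("stage landcover: ", sum(mask$eligible), " eligible cells of ",
          length(mask$eligible))

  spec <- resample_spec(config$resample$interval_min,
                        config$resample$tolerance_min)
  thinned <- resample_tracks(tracks, spec)
  message("stage resample: ", nrow(thinned), " fixes kept of ", nrow(tracks))

  window <- config_season(config$season)
  usage <- tally_usage(thinned, grid, window)
  message("stage tally: ", nrow(usage), " cells used in ", window$label)
  write_usage(usage, file.path(out, "usage.csv"))

  crit <- config_criteria(config$criteria)
  res <- designate_sites(usage, mask, crit)
  message("stage designate: ", nrow(res$pairs), " pair(s), ",
          nrow(res$unpaired_hotspots), " unpaired, ",
          nrow(res$rejected_hotspots), " rejected")

  write_sites(res, file.path(out, "sites.csv"))
  geojson_write_points(pairs_to_sites(res$pairs),
                       file.path(out, "sites.geojson"))
  utils::write.csv(res$rejected_hotspots, file.path(out, "rejected.csv"),
                   row.names = FALSE)
  utils::write.csv(res$unpaired_hotspots, file.path(out, "unpaired.csv"),
                   row.names = FALSE)
  yaml::write_yaml(config, file.path(out, "resolved_config.yaml"))
  invisible(res)
}

#' Run the full study: designation, survey models, persistence
#'
#' Runs [run_designation()], then fits the single-predictor binomial GLMs on
#' the configured survey tables (written to `table1.csv`) and, when a
#' `persistence` block is configured, the Wilcoxon persistence comparisons
#' across years (`table2.csv`), plus a plain-text `summary.txt`.
#'
#' @param config a [run_config()] (or path / list accepted by it).
#' @return list with `designation`, `table1`, `table2` (NULL when not
#'   configured), invisibly.
#' @export
run_full_study <- function(config) {
  config <- run_config(config)
  res <- run_designation(config)
  out <- config$out

  table1 <- NULL
  if (!is.null(config$surveys)) {
    surveys <- list()
    for (grp in c("birds", "small_mammals", "amphibians", "plants")) {
      p <- config$surveys[[grp]]
      if (!is.null(p)) {
        if (!file.exists(p)) stop("config stage 'surveys': file not found: ", p)
        surveys[[grp]] <- utils::read.csv(p, stringsAsFactors = FALSE)
      }
    }
    ptab <- aggregate_surveys(surveys)
    table1 <- run_table1(ptab, standardize = isTRUE(config$standardize))
    utils::write.csv(table1, file.path(out, "table1.csv"), row.names = FALSE)
    message("stage stats: ", nrow(table1), " model(s) fitted")
  }

  table2 <- NULL
  if (!is.null(config$persistence)) {
    tracks <- read_tracks(config$tracks, column_map = config$tracks_column_map)
    spec <- resample_spec(config$resample$interval_min,
                          config$resample$tolerance_min)
    thinned <- resample_tracks(tracks, spec)
    usage_by_year <- list()
    for (s in config$persistence$seasons) {
      w <- season_window(as.character(s$year), s$start, s$end,
                         s$timezone %||% "UTC")
      usage_by_year[[as.character(s$year)]] <-
        tally_usage(thinned, res$grid, w)
    }
    table2 <- persistence_analysis(res$pairs, usage_by_year,
                                   config$persistence$designation_year)
    utils::write.csv(table2, file.path(out, "table2.csv"), row.names = FALSE)
    message("stage persistence: ", nrow(table2), " comparison(s)")
  }

  summary_lines <- c(
    sprintf("season: %s", config$season$label %||% "season"),
    sprintf("pairs designated: %d", nrow(res$pairs)),
    if (!is.null(table1)) {
      c("hotspot-vs-control models (standardized slopes):",
        sprintf("  %-20s beta %6.2f  p %6.4f  n %3d", table1$predictor,
                table1$beta, table1$p_value, table1$n))
    },
    if (!is.null(table2)) {
      c("persistence (Wilcoxon):",
        sprintf("  %d vs %d %-14s W %7.1f  p %6.4f", table2$designation_year,
                table2$comparison_year, table2$variable, table2$W, table2$p))
    })
  writeLines(summary_lines, file.path(out, "summary.txt"))
  invisible(list(designation = res, table1 = table1, table2 = table2))
}

#' Simulate a complete study to disk
#'
#' Generates a landscape, raptor tracks and surveys with known ground truth
#' and writes them in the file formats the pipeline consumes: `tracks.csv`,
#' `landcover.geojson`, `perches.geojson` (empty by default),
#' `surveys/*.csv`, `truth.csv` and a ready-to-run `config.yaml`.
#'
#' @param out_dir output directory (created).
#' @param seed master seed; the landscape, movement and survey seeds are
#'   derived from it.
#' @param landscape_args,movement_args,survey_args named lists of overrides
#'   for [generate_landscape()], [movement_config()] and
#'   [survey_effect_config()].
#' @return list with the simulated `landscape`, `tracks`, `designation`,
#'   `surveys`, invisibly.
#' @export
simulate_study <- function(out_dir, seed = 1, landscape_args = list(),
                           movement_args = list(), survey_args = list()) {
  dir.create(file.path(out_dir, "surveys"), showWarnings = FALSE,
             recursive = TRUE)
  landscape <- do.call(generate_landscape,
                       utils::modifyList(list(seed = seed), landscape_args))
  mcfg <- do.call(movement_config,
                  utils::modifyList(list(seed = seed + 1), movement_args))
  tracks <- generate_tracks(landscape, mcfg)
  thinned <- resample_tracks(tracks)
  usage <- tally_usage(thinned, landscape$grid, mcfg$season)
  res <- designate_sites(usage, landscape$mask)
  scfg <- do.call(survey_effect_config,
                  utils::modifyList(list(seed = seed + 2), survey_args))
  surveys <- generate_surveys(landscape, pairs_to_sites(res$pairs), scfg)

  write_tracks(tracks, file.path(out_dir, "tracks.csv"))
  geojson_write_polygons(landscape$polygons,
                         file.path(out_dir, "landcover.geojson"))
  geojson_write_points(data.frame(x = numeric(), y = numeric()),
                       file.path(out_dir, "perches.geojson"))
  for (grp in names(surveys)) {
    if (!is.null(surveys[[grp]])) {
      utils::write.csv(surveys[[grp]],
                       file.path(out_dir, "surveys", paste0(grp, ".csv")),
                       row.names = FALSE)
    }
  }
  write_ground_truth(ground_truth(landscape), file.path(out_dir, "truth.csv"))

  cfg <- list(
    seed = seed, out = file.path(out_dir, "results"),
    tracks = file.path(out_dir, "tracks.csv"),
    landcover = file.path(out_dir, "landcover.geojson"),
    perches = file.path(out_dir, "perches.geojson"),
    bbox = as.numeric(landscape$bbox), cell_size = landscape$cell_size,
    season = list(label = mcfg$season$label,
                  start = format(mcfg$season$start_date),
                  end = format(mcfg$season$end_date),
                  timezone = mcfg$season$timezone),
    surveys = stats::setNames(
      as.list(file.path(out_dir, "surveys",
                        paste0(names(surveys), ".csv"))), names(surveys)))
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(list(landscape = landscape, tracks = tracks, designation = res,
                 surveys = surveys))
}
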