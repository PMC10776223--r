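#' Build a track set from a data frame of GPS fixes
#'
#' A track set is the raw observational unit of the pipeline: one row per GPS
#' fix, each fix belonging to one tagged individual of one raptor species, with
#' coordinates in a projected metric CRS. The constructor sorts fixes by
#' individual and timestamp, drops exact duplicate rows, and validates the
#' basic contract (one species per individual, finite coordinates, strictly
#' increasing timestamps within an individual).
#'
#' @param fixes data frame with columns `individual_id`, `species`,
#'   `timestamp` (`POSIXct`, stored as UTC), `x`, `y` (metres).
#' @param crs_id identifier of the projected metric CRS the coordinates live
#'   in. Purely descriptive; all internal math assumes metres.
#' @return A `trackset`: a data frame with the five columns above, sorted by
#'   `(individual_id, timestamp)`, with attribute `crs_id`.
#' @export
track_set <- function(fixes, crs_id = "local-metric") {
  required <- c("individual_id", "species", "timestamp", "x", "y")
  miss <- setdiff(required, names(fixes))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  fixes <- as.data.frame(fixes)[required]
  fixes$individual_id <- as.character(fixes$individual_id)
  fixes$species <- as.character(fixes$species)
  if (!inherits(fixes$timestamp, "POSIXct")) {
    fixes$timestamp <- parse_timestamp(fixes$timestamp)
  }
  attr(fixes$timestamp, "tzone") <- "UTC"
  fixes$x <- as.numeric(fixes$x)
  fixes$y <- as.numeric(fixes$y)
  if (nrow(fixes) > 0 && !all(is.finite(fixes$x) & is.finite(fixes$y))) {
    stop("non-finite coordinates in fixes")
  }

  n0 <- nrow(fixes)
  fixes <- fixes[!duplicated(fixes), , drop = FALSE]
  if (nrow(fixes) < n0) {
    message(n0 - nrow(fixes), " exact duplicate fix(es) dropped")
  }
  fixes <- fixes[order(fixes$individual_id, fixes$timestamp), , drop = FALSE]

  # same individual+timestamp but different coordinates: keep the first
  same_t <- duplicated(fixes[c("individual_id", "timestamp")])
  if (any(same_t)) {
    warning(sum(same_t), " fix(es) with duplicated timestamp for the same ",
            "individual but different attributes; keeping the first")
    fixes <- fixes[!same_t, , drop = FALSE]
  }

  sp_per_ind <- tapply(fixes$species, fixes$individual_id,
                       function(s) length(unique(s)))
  if (length(sp_per_ind) > 0 && any(sp_per_ind > 1)) {
    stop("individual(s) mapped to more than one species: ",
         paste(names(sp_per_ind)[sp_per_ind > 1], collapse = ", "))
  }

  rownames(fixes) <- NULL
  structure(fixes, crs_id = crs_id, class = c("trackset", "data.frame"))
}

#' @export
print.trackset <- function(x, ...) {
  cat("<trackset> ", nrow(x), " fixes, ",
      length(unique(x$individual_id)), " individuals, ",
      length(unique(x$species)), " species, crs: ",
      attr(x, "crs_id"), "\n", sep = "")
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

parse_timestamp <- function(ts) {
  ts_chr <- as.character(ts)
  fmts <- c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  best <- NULL
  best_ok <- -1L
  for (f in fmts) {
    out <- as.POSIXct(strptime(ts_chr, f, tz = "UTC"), tz = "UTC")
    ok <- sum(!is.na(out))
    if (ok > best_ok) {
      best <- out
      best_ok <- ok
    }
  }
  bad <- which(is.na(best) & !is.na(ts_chr) & nzchar(ts_chr))
  if (length(bad) > 0) {
    stop("unparseable timestamp at row ", bad[1], ": '", ts_chr[bad[1]], "'")
  }
  best
}

#' Default and Movebank column mappings for track CSV files
#'
#' @return Named character vector mapping internal names to file column names.
#' @export
movebank_column_map <- function() {
  c(individual_id = "individual-local-identifier",
    species = "individual-taxon-canonical-name",
    timestamp = "timestamp",
    lon = "location-long",
    lat = "location-lat")
}

#' Read GPS tracks from a CSV file
#'
#' Reads a fix table with one row per GPS position. By default the file is
#' expected to carry columns `individual_id`, `species`, `timestamp`
#' (ISO 8601, UTC), `x`, `y` (projected metres). A custom `column_map` renames
#' file columns onto these internal names; [movebank_column_map()] covers the
#' Movebank CSV dialect (`location-long`/`location-lat`), in which case
#' coordinates are projected into a local metric frame with a simple
#' equirectangular projection around the data centroid.
#'
#' @param path CSV file path.
#' @param column_map named character vector `internal_name = file_column`;
#'   internal names among `individual_id`, `species`, `timestamp`, `x`, `y`
#'   (projected input) or `lon`, `lat` (geographic input).
#' @param crs_id CRS label stored on the result.
#' @return A [track_set()].
#' @export
read_tracks <- function(path, column_map = NULL, crs_id = "local-metric") {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(column_map)) {
    column_map <- c(individual_id = "individual_id", species = "species",
                    timestamp = "timestamp", x = "x", y = "y")
  }
  for (nm in names(column_map)) {
    if (!column_map[[nm]] %in% names(raw)) {
      stop("missing required column: ", column_map[[nm]],
           " (mapped to '", nm, "')")
    }
  }
  d <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                  lapply(column_map, function(cn) raw[[cn]]))
  names(d) <- names(column_map)
  if (all(c("lon", "lat") %in% names(d))) {
    xy <- project_lonlat(as.numeric(d$lon), as.numeric(d$lat))
    d$x <- xy$x
    d$y <- xy$y
    crs_id <- attr(xy, "crs_id")
    d$lon <- NULL
    d$lat <- NULL
  }
  track_set(d, crs_id = crs_id)
}

#' Project geographic coordinates to a local metric frame
#'
#' Equirectangular projection about a reference point (the data centroid by
#' default): adequate for study areas of a few tens of kilometres.
#'
#' @param lon,lat numeric degrees.
#' @param origin optional `c(lon0, lat0)` reference; defaults to the centroid.
#' @return data frame with `x`, `y` in metres and a `crs_id` attribute.
#' @export
project_lonlat <- function(lon, lat, origin = NULL) {
  if (is.null(origin)) origin <- c(mean(lon, na.rm = TRUE), mean(lat, na.rm = TRUE))
  r_earth <- 6371008.8
  to_rad <- pi / 180
  out <- data.frame(
    x = r_earth * cos(origin[2] * to_rad) * (lon - origin[1]) * to_rad,
    y = r_earth * (lat - origin[2]) * to_rad
  )
  attr(out, "crs_id") <- sprintf("local-equirect(%.5f,%.5f)", origin[1], origin[2])
  out
}

#' Write a track set back to CSV
#'
#' @param tracks a [track_set()].
#' @param path output file.
#' @export
write_tracks <- function(tracks, path) {
  d <- as.data.frame(tracks)
  d$timestamp <- format(d$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Temporal resampling (thinning) specification
#'
#' @param interval_min target fix interval in minutes (default 15, the
#'   interval used to equalize sampling effort across individuals whose tags
#'   recorded at anything from 3 to 60 minutes).
#' @param tolerance_min tolerance in minutes (default 2): a fix is accepted
#'   when at least `interval - tolerance` has elapsed since the last kept fix.
#' @return A `resample_spec` list.
#' @export
resample_spec <- function(interval_min = 15, tolerance_min = 2) {
  if (!(tolerance_min >= 0 && tolerance_min < interval_min)) {
    stop("need 0 <= tolerance < interval")
  }
  structure(list(interval_min = interval_min, tolerance_min = tolerance_min),
            class = "resample_spec")
}

#' Thin tracks to a common fix interval
#'
#' Greedy rule, applied per individual: the first fix is always kept; a later
#' fix is kept iff it is at least `interval - tolerance` after the previously
#' kept fix. This is the standard track-resampling scheme used to equalize
#' sampling effort before space-use tallies, and it is idempotent.
#'
#' @param tracks a [track_set()].
#' @param spec a [resample_spec()].
#' @return A thinned [track_set()] with attribute `resampled = TRUE`.
#' @export
resample_tracks <- function(tracks, spec = resample_spec()) {
  stopifnot(inherits(spec, "resample_spec"))
  gap <- (spec$interval_min - spec$tolerance_min) * 60
  keep <- logical(nrow(tracks))
  if (nrow(tracks) > 0) {
    tsec <- as.numeric(tracks$timestamp)
    ids <- tracks$individual_id
    last <- -Inf
    cur <- ids[1]
    for (i in seq_len(nrow(tracks))) {
      if (ids[i] != cur) {
        cur <- ids[i]
        last <- -Inf
      }
      if (tsec[i] - last >= gap) {
        keep[i] <- TRUE
        last <- tsec[i]
      }
    }
  }
  out <- tracks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "crs_id") <- attr(tracks, "crs_id")
  attr(out, "resampled") <- TRUE
  class(out) <- c("trackset", "data.frame")
  out
}

#' Define a season window
#'
#' @param label window name, e.g. `"spring2020"`.
#' @param start_date,end_date inclusive calendar dates (anything
#'   `as.Date()` accepts).
#' @param timezone timezone used to turn timestamps into calendar dates
#'   (default UTC).
#' @return A `season_window` list.
#' @export
season_window <- function(label, start_date, end_date, timezone = "UTC") {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (start_date > end_date) stop("start_date must be <= end_date")
  structure(list(label = label, start_date = start_date, end_date = end_date,
                 timezone = timezone),
            class = "season_window")
}

local_date <- function(timestamp, timezone = "UTC") {
  as.Date(format(timestamp, "%Y-%m-%d", tz = timezone))
}

#' Restrict a track set to a season window and bounding box
#'
#' Keeps fixes whose local calendar date falls in `[start_date, end_date]`
#' (inclusive) and, when `bbox` is given, whose coordinates fall inside the
#' half-open rectangle `x in [xmin, xmax), y in [ymin, ymax)`.
#'
#' @param tracks a [track_set()].
#' @param window a [season_window()].
#' @param bbox optional numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @return Filtered [track_set()].
#' @export
filter_window <- function(tracks, window, bbox = NULL) {
  stopifnot(inherits(window, "season_window"))
  keep <- rep(TRUE, nrow(tracks))
  if (nrow(tracks) > 0) {
    d <- local_date(tracks$timestamp, window$timezone)
    keep <- d >= window$start_date & d <= window$end_date
    if (!is.null(bbox)) {
      bbox <- as_bbox(bbox)
      keep <- keep &
        tracks$x >= bbox[1] & tracks$x < bbox[3] &
        tracks$y >= bbox[2] & tracks$y < bbox[4]
    }
  }
  out <- tracks[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "crs_id") <- attr(tracks, "crs_id")
  attr(out, "resampled") <- attr(tracks, "resampled")
  class(out) <- c("trackset", "data.frame")
  out
}

as_bbox <- function(bbox) {
  bbox <- as.numeric(bbox)
  if (length(bbox) != 4 || any(!is.finite(bbox))) {
    stop("bbox must be numeric c(xmin, ymin, xmax, ymax)")
  }
  if (bbox[3] <= bbox[1] || bbox[4] <= bbox[2]) {
    stop("bbox has zero or negative extent")
  }
  bbox
}
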