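#' Build the analysis grid over a bounding box
#'
#' The analysis grid is the spatial substrate of the whole pipeline: square
#' cells (50 m by default, a few times the GPS positioning error) indexed by
#' 0-based `(row, col)` from the lower-left origin. Cell `(r, c)` covers the
#' half-open square `[origin_x + c*s, origin_x + (c+1)*s) x
#' [origin_y + r*s, origin_y + (r+1)*s)`.
#'
#' @param bbox numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @param cell_size cell side in metres (default 50).
#' @return A `grid_spec` list with `origin_x`, `origin_y`, `cell_size`,
#'   `n_rows`, `n_cols`.
#' @export
build_grid <- function(bbox, cell_size = 50) {
  bbox <- as_bbox(bbox)
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0) {
    stop("cell_size must be a single positive number")
  }
  structure(list(
    origin_x = bbox[1], origin_y = bbox[2], cell_size = cell_size,
    n_rows = as.integer(ceiling((bbox[4] - bbox[2]) / cell_size)),
    n_cols = as.integer(ceiling((bbox[3] - bbox[1]) / cell_size))
  ), class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d rows x %d cols, cell %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y))
  invisible(x)
}

#' Cell centroid coordinates
#'
#' @param grid a [build_grid()] spec.
#' @param row,col 0-based cell indices (vectorized).
#' @return data frame with `x`, `y` centroid coordinates in metres.
#' @export
cell_centroid <- function(grid, row, col) {
  data.frame(x = grid$origin_x + (col + 0.5) * grid$cell_size,
             y = grid$origin_y + (row + 0.5) * grid$cell_size)
}

#' Assign fixes to grid cells
#'
#' Half-open cell convention: a fix exactly on a cell's upper or right edge
#' belongs to the next cell. Fixes outside the grid extent are dropped and
#' their count reported.
#'
#' @param tracks a [track_set()] (or any data frame with `x`, `y`).
#' @param grid a [build_grid()] spec.
#' @return The input rows that fall on the grid, with integer columns `row`
#'   and `col` appended.
#' @export
assign_fixes <- function(tracks, grid) {
  d <- as.data.frame(tracks)
  row <- floor((d$y - grid$origin_y) / grid$cell_size)
  col <- floor((d$x - grid$origin_x) / grid$cell_size)
  inside <- row >= 0 & row < grid$n_rows & col >= 0 & col < grid$n_cols
  if (any(!inside)) {
    message(sum(!inside), " fix(es) outside grid extent dropped")
  }
  d <- d[inside, , drop = FALSE]
  d$row <- as.integer(row[inside])
  d$col <- as.integer(col[inside])
  rownames(d) <- NULL
  d
}

#' Construct a usage table
#'
#' Mostly used internally by [tally_usage()]; exposed so that usage tables can
#' be built directly (e.g. in simulations or when importing tallies computed
#' elsewhere). Cells with no usage are implicit: lookups return zeros.
#'
#' @param usage data frame with integer columns `row`, `col`, `n_obs`,
#'   `n_individuals`, `n_species`, `n_days`.
#' @param grid the [build_grid()] spec the cells refer to.
#' @param period label of the season the tallies cover.
#' @return A `usage_table` data frame with attributes `grid` and `period`.
#' @export
usage_table <- function(usage, grid, period = "season") {
  required <- c("row", "col", "n_obs", "n_individuals", "n_species", "n_days")
  miss <- setdiff(required, names(usage))
  if (length(miss) > 0) stop("missing usage column(s): ", paste(miss, collapse = ", "))
  usage <- as.data.frame(usage)[required]
  for (nm in required) usage[[nm]] <- as.integer(usage[[nm]])
  if (nrow(usage) > 0) {
    if (any(usage$row < 0 | usage$row >= grid$n_rows |
            usage$col < 0 | usage$col >= grid$n_cols)) {
      stop("usage keyed to cells off the grid")
    }
    bad <- usage$n_species > usage$n_individuals |
      usage$n_individuals > usage$n_obs | usage$n_days > usage$n_obs |
      usage$n_obs < 0
    if (any(bad)) stop("usage counts violate n_species <= n_individuals <= n_obs")
    if (anyDuplicated(usage[c("row", "col")]) > 0) stop("duplicate cells in usage")
  }
  usage <- usage[order(usage$row, usage$col), , drop = FALSE]
  rownames(usage) <- NULL
  structure(usage, grid = grid, period = period,
            class = c("usage_table", "data.frame"))
}

#' Tally per-cell raptor usage for a season
#'
#' For every grid cell visited, counts the number of (resampled) fixes, of
#' distinct individuals, of distinct species, and of distinct local calendar
#' days with at least one fix ("revisits"). Tracks should already be thinned
#' to the common interval (see [resample_tracks()]) so the tallies are not
#' dominated by the best-charging tags.
#'
#' @param tracks a [track_set()].
#' @param grid a [build_grid()] spec.
#' @param window optional [season_window()]; when given, fixes are first
#'   restricted to it (dates in the window's timezone).
#' @param require_resampled assert that `tracks` has been through
#'   [resample_tracks()] (default TRUE).
#' @return A [usage_table()].
#' @export
tally_usage <- function(tracks, grid, window = NULL, require_resampled = TRUE) {
  if (require_resampled && !isTRUE(attr(tracks, "resampled"))) {
    stop("tracks are not resampled; run resample_tracks() first ",
         "or set require_resampled = FALSE")
  }
  tz <- if (is.null(window)) "UTC" else window$timezone
  if (!is.null(window)) tracks <- filter_window(tracks, window)
  period <- if (is.null(window)) "all" else window$label
  d <- assign_fixes(tracks, grid)
  if (nrow(d) == 0) {
    return(usage_table(data.frame(row = integer(), col = integer(),
                                  n_obs = integer(), n_individuals = integer(),
                                  n_species = integer(), n_days = integer()),
                       grid, period))
  }
  key <- d$row * grid$n_cols + d$col
  ukey <- sort(unique(key))
  idx <- match(key, ukey)
  n_obs <- tabulate(idx, nbins = length(ukey))
  count_distinct <- function(v) {
    first <- !duplicated(cbind(idx, v))
    tabulate(idx[first], nbins = length(ukey))
  }
  n_individuals <- count_distinct(d$individual_id)
  n_species <- count_distinct(d$species)
  n_days <- count_distinct(as.character(local_date(d$timestamp, tz)))
  usage_table(data.frame(
    row = as.integer(ukey %/% grid$n_cols),
    col = as.integer(ukey %% grid$n_cols),
    n_obs = n_obs, n_individuals = n_individuals,
    n_species = n_species, n_days = n_days
  ), grid, period)
}

#' Look up usage at cells, zeros when unused
#'
#' @param usage a [usage_table()].
#' @param row,col 0-based cell indices (vectorized).
#' @return data frame of `n_obs`, `n_individuals`, `n_species`, `n_days`,
#'   one row per queried cell, all-zero rows for cells absent from the table.
#' @export
usage_at_cell <- function(usage, row, col) {
  grid <- attr(usage, "grid")
  i <- match(row * grid$n_cols + col, usage$row * grid$n_cols + usage$col)
  out <- data.frame(n_obs = integer(length(i)), n_individuals = integer(length(i)),
                    n_species = integer(length(i)), n_days = integer(length(i)))
  hit <- !is.na(i)
  for (nm in names(out)) out[[nm]][hit] <- usage[[nm]][i[hit]]
  out
}

#' Write / read a usage table as CSV
#'
#' @param usage a [usage_table()].
#' @param path file path.
#' @export
write_usage <- function(usage, path) {
  d <- as.data.frame(usage)
  d <- cbind(period = attr(usage, "period"), d)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_usage
#' @param grid grid spec the stored cells refer to.
#' @export
read_usage <- function(path, grid) {
  d <- utils::read.csv(path)
  usage_table(d, grid, period = if ("period" %in% names(d)) d$period[1] else "season")
}
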