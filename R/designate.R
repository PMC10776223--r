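#' Criteria controlling hotspot and control-site designation
#'
#' Defaults follow the field protocol: a cell qualifies as an activity hotspot
#' when at least three different tracked individuals of at least two different
#' raptor species used it in a season; competing hotspots closer than 450 m to
#' a chosen one are discarded (the bird-survey detectability radius makes
#' closer sites non-independent); each hotspot gets a matched farmland control
#' on the 500 m buffer around its centroid, at least 500 m from every other
#' designated site and with at most one tracked-raptor observation.
#'
#' @param min_individuals minimum distinct individuals in a cell (default 3).
#' @param min_species minimum distinct species (default 2).
#' @param min_hotspot_spacing minimum distance between chosen hotspots in
#'   metres; competitors strictly closer are discarded (default 450).
#' @param control_radius buffer radius at which controls are sought (450)
#'   (default 500 m from the hotspot centroid).
#' @param min_control_spacing minimum distance from a control to every other
#'   designated site of the season (default 500); the paired hotspot itself,
#'   definitionally at `control_radius`, is exempt.
#' @param max_control_obs maximum tracked-raptor observations tolerated in a
#'   control cell (default 1).
#' @param connectivity 8 (queen, default) or 4 (rook) adjacency used to group
#'   neighbouring qualifying cells before picking one representative.
#' @return A `hotspot_criteria` list.
#' @export
hotspot_criteria <- function(min_individuals = 3, min_species = 2,
                             min_hotspot_spacing = 450, control_radius = 500,
                             min_control_spacing = 500, max_control_obs = 1,
                             connectivity = 8) {
  stopifnot(min_individuals >= 1, min_species >= 1,
            min_species <= min_individuals,
            min_hotspot_spacing > 0, control_radius > 0,
            min_control_spacing > 0, max_control_obs >= 0,
            connectivity %in% c(4, 8))
  structure(as.list(environment()), class = "hotspot_criteria")
}

# ranking used everywhere a "better" cell must win: more species first, then
# more individuals, then more observations, then lexicographically smallest
# (row, col) for determinism
rank_order <- function(d) {
  order(-d$n_species, -d$n_individuals, -d$n_obs, d$row, d$col)
}

#' Qualify grid cells as hotspot candidates
#'
#' A cell qualifies iff it is eligible landcover, carries no perch flag, and
#' was used by at least `min_individuals` distinct individuals of at least
#' `min_species` distinct species. Qualifying cells rejected only for their
#' perch flag are recorded in the `rejected` attribute (reason `"perch"`).
#'
#' @param usage a [usage_table()].
#' @param mask a [rasterize_landcover()] / [landcover_mask()] result.
#' @param crit a [hotspot_criteria()].
#' @return data frame of candidate cells with their usage counts; attribute
#'   `rejected` lists perch-rejected cells.
#' @export
qualify_cells <- function(usage, mask, crit = hotspot_criteria()) {
  meets <- usage$n_individuals >= crit$min_individuals &
    usage$n_species >= crit$min_species
  elig <- mask$eligible[cbind(usage$row + 1, usage$col + 1)]
  perch <- mask$perch[cbind(usage$row + 1, usage$col + 1)]
  out <- as.data.frame(usage)[meets & elig & !perch, , drop = FALSE]
  rej <- as.data.frame(usage)[meets & elig & perch, c("row", "col"), drop = FALSE]
  rej$reason <- if (nrow(rej) > 0) "perch" else character(0)
  rownames(out) <- rownames(rej) <- NULL
  attr(out, "rejected") <- rej
  out
}

#' Resolve adjacent candidate cells to one representative each
#'
#' Qualifying cells in adjacent position (touching under the configured
#' connectivity) describe one activity centre; the representative is the cell
#' with the highest number of species, ties broken by more individuals, then
#' more observations, then the lexicographically smallest `(row, col)`.
#'
#' @param candidates output of [qualify_cells()].
#' @param crit a [hotspot_criteria()].
#' @return data frame of representative cells; attribute `rejected` lists the
#'   non-representative members (reason `"adjacent"`).
#' @export
resolve_adjacent <- function(candidates, crit = hotspot_criteria()) {
  d <- as.data.frame(candidates)
  if (nrow(d) == 0) {
    attr(d, "rejected") <- data.frame(row = integer(), col = integer(),
                                      reason = character())
    return(d)
  }
  if (crit$connectivity == 8) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0)
    dc <- c(0, 0, -1, 1)
  }
  key <- paste(d$row, d$col)
  comp <- rep(NA_integer_, nrow(d))
  ncomp <- 0L
  for (i in seq_len(nrow(d))) {
    if (!is.na(comp[i])) next
    ncomp <- ncomp + 1L
    queue <- i
    comp[i] <- ncomp
    while (length(queue) > 0) {
      j <- queue[[1]]
      queue <- queue[-1]
      nb <- match(paste(d$row[j] + dr, d$col[j] + dc), key)
      nb <- nb[!is.na(nb)]
      nb <- nb[is.na(comp[nb])]
      comp[nb] <- ncomp
      queue <- c(queue, nb)
    }
  }
  reps <- logical(nrow(d))
  for (g in seq_len(ncomp)) {
    members <- which(comp == g)
    reps[members[rank_order(d[members, , drop = FALSE])[1]]] <- TRUE
  }
  out <- d[reps, , drop = FALSE]
  rej <- d[!reps, c("row", "col"), drop = FALSE]
  rej$reason <- if (nrow(rej) > 0) "adjacent" else character(0)
  rownames(out) <- rownames(rej) <- NULL
  attr(out, "rejected") <- rej
  out
}

#' Enforce minimum spacing between hotspots
#'
#' Representatives are processed in rank order (species, individuals,
#' observations, cell index); one is accepted unless its centroid lies
#' strictly closer than `min_hotspot_spacing` to an already-accepted hotspot
#' ("closer than" - a pair at exactly the threshold distance is allowed).
#'
#' @param reps output of [resolve_adjacent()].
#' @param grid the [build_grid()] spec (for centroids).
#' @param crit a [hotspot_criteria()].
#' @return data frame of accepted hotspot cells with centroid columns `x`,
#'   `y`; attribute `rejected` lists spacing casualties (reason `"spacing"`).
#' @export
enforce_spacing <- function(reps, grid, crit = hotspot_criteria()) {
  d <- as.data.frame(reps)
  d <- d[rank_order(d), , drop = FALSE]
  cen <- cell_centroid(grid, d$row, d$col)
  d$x <- cen$x
  d$y <- cen$y
  accept <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!any(accept)) {
      accept[i] <- TRUE
      next
    }
    a <- which(accept)
    dist <- sqrt((d$x[a] - d$x[i])^2 + (d$y[a] - d$y[i])^2)
    accept[i] <- all(dist >= crit$min_hotspot_spacing)
  }
  out <- d[accept, , drop = FALSE]
  rej <- d[!accept, c("row", "col"), drop = FALSE]
  rej$reason <- if (nrow(rej) > 0) "spacing" else character(0)
  rownames(out) <- rownames(rej) <- NULL
  attr(out, "rejected") <- rej
  out
}

#' Cells intersected by a buffer circle, in clockwise azimuth order
#'
#' Lists every grid cell whose square is intersected by the circle of the
#' given radius centred on a cell's centroid (i.e. the cell touches the buffer
#' boundary), ordered by the azimuth of the cell centroid clockwise from
#' north, starting at 0 degrees; azimuth ties are broken by nearer centroid,
#' then by cell index. The scan is truncated at the grid edge.
#'
#' @param cell `c(row, col)` of the centre cell (0-based).
#' @param grid a [build_grid()] spec.
#' @param radius buffer radius in metres (> cell size).
#' @return data frame `row`, `col`, `azimuth_deg`, `dist` (centroid distance).
#' @export
ring_cells <- function(cell, grid, radius) {
  stopifnot(radius > grid$cell_size)
  s <- grid$cell_size
  h <- cell_centroid(grid, cell[1], cell[2])
  r0 <- max(0L, as.integer(floor((h$y - radius - s) / s - grid$origin_y / s)))
  r1 <- min(grid$n_rows - 1L, as.integer(ceiling((h$y + radius - grid$origin_y) / s)))
  c0 <- max(0L, as.integer(floor((h$x - radius - s - grid$origin_x) / s)))
  c1 <- min(grid$n_cols - 1L, as.integer(ceiling((h$x + radius - grid$origin_x) / s)))
  if (r1 < r0 || c1 < c0) {
    return(data.frame(row = integer(), col = integer(),
                      azimuth_deg = numeric(), dist = numeric()))
  }
  g <- expand.grid(row = r0:r1, col = c0:c1)
  x0 <- grid$origin_x + g$col * s
  y0 <- grid$origin_y + g$row * s
  # min and max distance from the hotspot centroid to the cell square
  dx <- pmax(pmax(x0 - h$x, h$x - (x0 + s)), 0)
  dy <- pmax(pmax(y0 - h$y, h$y - (y0 + s)), 0)
  dmin <- sqrt(dx^2 + dy^2)
  fx <- pmax(abs(h$x - x0), abs(h$x - (x0 + s)))
  fy <- pmax(abs(h$y - y0), abs(h$y - (y0 + s)))
  dmax <- sqrt(fx^2 + fy^2)
  on_ring <- dmin <= radius & dmax >= radius
  g <- g[on_ring, , drop = FALSE]
  cen <- cell_centroid(grid, g$row, g$col)
  g$azimuth_deg <- (atan2(cen$x - h$x, cen$y - h$y) * 180 / pi) %% 360
  g$dist <- sqrt((cen$x - h$x)^2 + (cen$y - h$y)^2)
  g <- g[order(g$azimuth_deg, g$dist, g$row, g$col), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Select the matched control site for one hotspot
#'
#' Walks the 500 m buffer ring clockwise from due north and returns the first
#' cell that (1) has at most `max_control_obs` tracked-raptor observations in
#' the season, (2) is farmland without a perch structure, and (3) lies at
#' least `min_control_spacing` from every already-designated site of the
#' season other than its own hotspot. Returns NULL when the ring is exhausted
#' (the hotspot stays unpaired; the buffer radius is never relaxed).
#'
#' @param hotspot one-row data frame with `row`, `col`, `x`, `y`.
#' @param usage a [usage_table()].
#' @param mask a landcover mask.
#' @param taken data frame of already-designated site centroids (`x`, `y`),
#'   including all hotspots of the season and previously chosen controls.
#' @param crit a [hotspot_criteria()].
#' @return one-row data frame `row`, `col`, `x`, `y`, `azimuth_deg`,
#'   `n_obs`, or NULL.
#' @export
select_control <- function(hotspot, usage, mask, taken, crit = hotspot_criteria()) {
  grid <- attr(usage, "grid")
  ring <- ring_cells(c(hotspot$row, hotspot$col), grid, crit$control_radius)
  if (nrow(ring) == 0) return(NULL)
  u <- usage_at_cell(usage, ring$row, ring$col)
  farm <- mask$farmland[cbind(ring$row + 1, ring$col + 1)] &
    !mask$perch[cbind(ring$row + 1, ring$col + 1)]
  cen <- cell_centroid(grid, ring$row, ring$col)
  ok <- u$n_obs <= crit$max_control_obs & farm
  if (!is.null(taken) && nrow(taken) > 0) {
    not_self <- !(abs(taken$x - hotspot$x) < 1e-9 & abs(taken$y - hotspot$y) < 1e-9)
    tk <- taken[not_self, , drop = FALSE]
    if (nrow(tk) > 0) {
      for (i in which(ok)) {
        dist <- sqrt((tk$x - cen$x[i])^2 + (tk$y - cen$y[i])^2)
        if (any(dist < crit$min_control_spacing)) ok[i] <- FALSE
      }
    }
  }
  i <- which(ok)[1]
  if (is.na(i)) return(NULL)
  data.frame(row = ring$row[i], col = ring$col[i],
             x = cen$x[i], y = cen$y[i],
             azimuth_deg = ring$azimuth_deg[i], n_obs = u$n_obs[i])
}

#' Designate activity hotspots and matched control sites
#'
#' The full designation procedure: qualify cells, collapse adjacent
#' qualifiers to representatives, enforce the 450 m hotspot spacing in rank
#' order, then - again in rank order - find each hotspot's control on its
#' 500 m buffer, the set of taken sites growing as controls are chosen.
#' Deterministic for identical inputs.
#'
#' @param usage a [usage_table()] built from resampled tracks of the season.
#' @param mask a landcover mask on the same grid.
#' @param crit a [hotspot_criteria()].
#' @param season label stored on the result (defaults to the usage period).
#' @return A `designation_result` list: `pairs` (one row per hotspot-control
#'   pair), `unpaired_hotspots`, `rejected_hotspots` (with reasons), plus the
#'   criteria and season.
#' @export
designate_sites <- function(usage, mask, crit = hotspot_criteria(),
                            season = attr(usage, "period")) {
  grid <- attr(usage, "grid")
  stopifnot(identical(dim(mask$eligible), c(grid$n_rows, grid$n_cols)))
  cand <- qualify_cells(usage, mask, crit)
  reps <- resolve_adjacent(cand, crit)
  hs <- enforce_spacing(reps, grid, crit)
  rejected <- rbind(attr(cand, "rejected"), attr(reps, "rejected"),
                    attr(hs, "rejected"))
  if (nrow(hs) == 0) {
    message("no cell meets the hotspot criteria; empty designation")
  }

  taken <- hs[c("x", "y")]
  pairs <- list()
  unpaired <- list()
  for (i in seq_len(nrow(hs))) {
    ctrl <- select_control(hs[i, ], usage, mask, taken, crit)
    if (is.null(ctrl)) {
      unpaired[[length(unpaired) + 1]] <-
        data.frame(row = hs$row[i], col = hs$col[i], reason = "ring_exhausted")
      next
    }
    taken <- rbind(taken, ctrl[c("x", "y")])
    pairs[[length(pairs) + 1]] <- data.frame(
      season = season,
      hotspot_row = hs$row[i], hotspot_col = hs$col[i],
      hotspot_x = hs$x[i], hotspot_y = hs$y[i],
      n_obs = hs$n_obs[i], n_individuals = hs$n_individuals[i],
      n_species = hs$n_species[i], n_days = hs$n_days[i],
      control_row = ctrl$row, control_col = ctrl$col,
      control_x = ctrl$x, control_y = ctrl$y,
      azimuth_deg = ctrl$azimuth_deg, control_n_obs = ctrl$n_obs
    )
  }
  pairs <- if (length(pairs) > 0) do.call(rbind, pairs) else empty_pairs(season)
  unpaired <- if (length(unpaired) > 0) do.call(rbind, unpaired) else
    data.frame(row = integer(), col = integer(), reason = character())
  rownames(pairs) <- rownames(unpaired) <- NULL
  structure(list(pairs = pairs, unpaired_hotspots = unpaired,
                 rejected_hotspots = rejected, criteria = crit,
                 season = season, grid = grid),
            class = "designation_result")
}

empty_pairs <- function(season) {
  data.frame(season = character(), hotspot_row = integer(),
             hotspot_col = integer(), hotspot_x = numeric(),
             hotspot_y = numeric(), n_obs = integer(),
             n_individuals = integer(), n_species = integer(),
             n_days = integer(), control_row = integer(),
             control_col = integer(), control_x = numeric(),
             control_y = numeric(), azimuth_deg = numeric(),
             control_n_obs = integer())
}

#' @export
print.designation_result <- function(x, ...) {
  cat(sprintf("<designation_result> season %s: %d pair(s), %d unpaired, %d rejected\n",
              x$season, nrow(x$pairs), nrow(x$unpaired_hotspots),
              nrow(x$rejected_hotspots)))
  invisible(x)
}

#' Export designated site pairs
#'
#' `write_sites` writes one row per site (hotspot and control) as CSV;
#' `sites_to_geojson` writes the same sites as a GeoJSON FeatureCollection of
#' point features.
#'
#' @param result a [designate_sites()] result.
#' @param path output file.
#' @export
write_sites <- function(result, path) {
  utils::write.csv(pairs_to_sites(result$pairs), path, row.names = FALSE)
  invisible(path)
}

#' Flatten a pairs table to one row per site
#'
#' @param pairs the `pairs` data frame of a [designate_sites()] result.
#' @return data frame with `plot_id`, `kind`, `season`, `row`, `col`, `x`, `y`.
#' @export
pairs_to_sites <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(data.frame(plot_id = character(), kind = character(),
                      season = character(), row = integer(), col = integer(),
                      x = numeric(), y = numeric()))
  }
  id <- sprintf("pair%02d", seq_len(nrow(pairs)))
  rbind(
    data.frame(plot_id = paste0(id, "_H"), kind = "hotspot",
               season = pairs$season, row = pairs$hotspot_row,
               col = pairs$hotspot_col, x = pairs$hotspot_x, y = pairs$hotspot_y),
    data.frame(plot_id = paste0(id, "_C"), kind = "control",
               season = pairs$season, row = pairs$control_row,
               col = pairs$control_col, x = pairs$control_x, y = pairs$control_y)
  )
}
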