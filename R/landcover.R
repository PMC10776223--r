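#' Landcover classes understood by the pipeline
#'
#' Open classes (`farmland`, `other_open`) are eligible for hotspot
#' designation; `forest`, `water` and `peatland` are the subtracted layers.
#' Controls are additionally restricted to `farmland`.
#'
#' @return character vector of the recognized class labels.
#' @export
landcover_classes <- function() {
  c("farmland", "other_open", "forest", "water", "peatland")
}

blocked_classes <- function() c("forest", "water", "peatland")

#' Rasterize classed landcover polygons onto the analysis grid
#'
#' Each cell is classified by the landcover class with the largest area
#' overlap. Polygons are given in long form (one row per vertex); area not
#' covered by any polygon takes the `background` class, so a typical farmland
#' mosaic is described by forest/water/peatland (and optional `other_open`)
#' patches over a farmland background. Overlapping polygons are not resolved
#' (areas would double-count); supply non-overlapping patches.
#'
#' A cell is *eligible* iff its largest-overlap class is not forest, water or
#' peatland; it is *farmland* iff that class is `farmland`. An exact tie for
#' the largest class makes the cell ineligible (conservative). Cells
#' containing an isolated perch structure (single tree, pylon...) are flagged
#' so designation can discard them: at the 50 m scale such structures attract
#' perching rather than foraging raptors.
#'
#' @param grid a [build_grid()] spec.
#' @param polygons data frame with columns `poly_id`, `class`, `x`, `y`
#'   (vertices in ring order), or NULL for background-only.
#' @param perch_points optional data frame with `x`, `y` of perch structures.
#' @param background class assumed where no polygon covers (default
#'   `"farmland"`).
#' @return A `landcover_mask`: list of logical matrices `eligible`,
#'   `farmland`, `perch` (rows = grid rows, 1-based indexing of 0-based cells)
#'   plus the grid.
#' @export
rasterize_landcover <- function(grid, polygons = NULL, perch_points = NULL,
                                background = "farmland") {
  classes <- landcover_classes()
  if (!background %in% classes) stop("unknown background class: ", background)
  s <- grid$cell_size
  cell_area <- s * s
  nr <- grid$n_rows; nc <- grid$n_cols
  # per-class accumulated overlap area
  area <- lapply(classes, function(cl) matrix(0, nr, nc))
  names(area) <- classes

  if (!is.null(polygons) && nrow(polygons) > 0) {
    bad <- setdiff(unique(polygons$class), classes)
    if (length(bad) > 0) {
      stop("unknown landcover class label(s): ", paste(bad, collapse = ", "))
    }
    for (pid in unique(polygons$poly_id)) {
      p <- polygons[polygons$poly_id == pid, , drop = FALSE]
      cl <- p$class[1]
      xy <- cbind(p$x, p$y)
      # cells possibly touched by the polygon bbox
      c0 <- max(0L, floor((min(xy[, 1]) - grid$origin_x) / s))
      c1 <- min(nc - 1L, floor((max(xy[, 1]) - grid$origin_x - 1e-12) / s))
      r0 <- max(0L, floor((min(xy[, 2]) - grid$origin_y) / s))
      r1 <- min(nr - 1L, floor((max(xy[, 2]) - grid$origin_y - 1e-12) / s))
      if (c1 < c0 || r1 < r0) next
      if (is_axis_rect(xy)) {
        px0 <- min(xy[, 1]); px1 <- max(xy[, 1])
        py0 <- min(xy[, 2]); py1 <- max(xy[, 2])
        cols <- c0:c1; rows <- r0:r1
        wx <- interval_overlap(grid$origin_x + cols * s,
                               grid$origin_x + (cols + 1) * s, px0, px1)
        wy <- interval_overlap(grid$origin_y + rows * s,
                               grid$origin_y + (rows + 1) * s, py0, py1)
        area[[cl]][rows + 1, cols + 1] <-
          area[[cl]][rows + 1, cols + 1] + outer(wy, wx)
      } else {
        for (r in r0:r1) for (cc in c0:c1) {
          rect <- c(grid$origin_x + cc * s, grid$origin_y + r * s,
                    grid$origin_x + (cc + 1) * s, grid$origin_y + (r + 1) * s)
          a <- polygon_area(clip_polygon_rect(xy, rect))
          if (a > 0) area[[cl]][r + 1, cc + 1] <- area[[cl]][r + 1, cc + 1] + a
        }
      }
    }
  }

  covered <- Reduce(`+`, area)
  area[[background]] <- area[[background]] + pmax(0, cell_area - covered)

  stacked <- vapply(classes, function(cl) as.vector(area[[cl]]),
                    numeric(nr * nc))
  stacked <- matrix(stacked, nrow = nr * nc, ncol = length(classes))
  amax <- apply(stacked, 1, max)
  n_at_max <- rowSums(abs(stacked - amax) < 1e-6)
  argmax <- classes[max.col(stacked, ties.method = "first")]
  tie <- n_at_max > 1
  eligible <- !tie & !(argmax %in% blocked_classes())
  farmland <- !tie & argmax == "farmland"

  perch <- matrix(FALSE, nr, nc)
  if (!is.null(perch_points) && nrow(perch_points) > 0) {
    pp <- assign_fixes(perch_points, grid)
    if (nrow(pp) > 0) perch[cbind(pp$row + 1, pp$col + 1)] <- TRUE
  }

  structure(list(eligible = matrix(eligible, nr, nc),
                 farmland = matrix(farmland, nr, nc),
                 perch = perch,
                 class_of = matrix(ifelse(tie, NA_character_, argmax), nr, nc),
                 grid = grid),
            class = "landcover_mask")
}

#' Construct a landcover mask directly from logical matrices
#'
#' Useful in simulations and tests where the per-cell classification is
#' already known.
#'
#' @param grid a [build_grid()] spec.
#' @param eligible,farmland,perch logical matrices `n_rows x n_cols`
#'   (defaults: all eligible farmland, no perches).
#' @return A `landcover_mask`.
#' @export
landcover_mask <- function(grid, eligible = NULL, farmland = NULL, perch = NULL) {
  nr <- grid$n_rows; nc <- grid$n_cols
  if (is.null(eligible)) eligible <- matrix(TRUE, nr, nc)
  if (is.null(farmland)) farmland <- eligible
  if (is.null(perch)) perch <- matrix(FALSE, nr, nc)
  stopifnot(all(dim(eligible) == c(nr, nc)), all(dim(farmland) == c(nr, nc)),
            all(dim(perch) == c(nr, nc)))
  if (any(farmland & !eligible)) stop("farmland cells must be eligible")
  structure(list(eligible = eligible, farmland = farmland, perch = perch,
                 class_of = matrix(ifelse(farmland, "farmland",
                                          ifelse(eligible, "other_open", "forest")),
                                   nr, nc),
                 grid = grid),
            class = "landcover_mask")
}

#' @export
print.landcover_mask <- function(x, ...) {
  cat(sprintf("<landcover_mask> %d x %d cells: %.1f%% eligible, %.1f%% farmland, %d perch cell(s)\n",
              nrow(x$eligible), ncol(x$eligible),
              100 * mean(x$eligible), 100 * mean(x$farmland), sum(x$perch)))
  invisible(x)
}
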