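# Minimal computational geometry used by the landcover rasterizer:
# polygon area (shoelace) and polygon-vs-axis-aligned-rectangle clipping
# (Sutherland-Hodgman). Vertices are plain matrices with columns x, y; rings
# may be given open or closed and in either winding.

polygon_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# clip a polygon to rect c(xmin, ymin, xmax, ymax); returns vertex matrix
clip_polygon_rect <- function(xy, rect) {
  clip_edge <- function(pts, keep, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- vector("list", 2L * n)
    k <- 0L
    prev <- pts[n, ]
    prev_in <- keep(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- keep(cur)
      if (cur_in) {
        if (!prev_in) { k <- k + 1L; out[[k]] <- intersect(prev, cur) }
        k <- k + 1L; out[[k]] <- cur
      } else if (prev_in) {
        k <- k + 1L; out[[k]] <- intersect(prev, cur)
      }
      prev <- cur
      prev_in <- cur_in
    }
    if (k == 0L) return(pts[0, , drop = FALSE])
    do.call(rbind, out[seq_len(k)])
  }
  lerp <- function(p, q, t) p + t * (q - p)
  at_x <- function(bound) function(p, q) lerp(p, q, (bound - p[1]) / (q[1] - p[1]))
  at_y <- function(bound) function(p, q) lerp(p, q, (bound - p[2]) / (q[2] - p[2]))
  pts <- xy
  pts <- clip_edge(pts, function(p) p[1] >= rect[1], at_x(rect[1]))
  pts <- clip_edge(pts, function(p) p[1] <= rect[3], at_x(rect[3]))
  pts <- clip_edge(pts, function(p) p[2] >= rect[2], at_y(rect[2]))
  pts <- clip_edge(pts, function(p) p[2] <= rect[4], at_y(rect[4]))
  pts
}

# TRUE when a ring is an axis-aligned rectangle (enables the fast overlap path)
is_axis_rect <- function(xy) {
  xy <- unique(round(xy, 9))
  nrow(xy) == 4 && length(unique(xy[, 1])) == 2 && length(unique(xy[, 2])) == 2
}

interval_overlap <- function(a0, a1, b0, b1) {
  pmax(0, pmin(a1, b1) - pmax(a0, b0))
}
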