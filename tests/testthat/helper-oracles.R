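# Independent reference implementations used as test oracles. They share the
# semantics of the package functions but none of their code: plain loops,
# different geometry formulations, exhaustive enumeration where feasible.

# ---- designation: brute-force reference ------------------------------------

oracle_designate <- function(usage, mask, crit) {
  grid <- attr(usage, "grid")
  u <- as.data.frame(usage)
  s <- grid$cell_size
  centroid <- function(r, c) c(grid$origin_x + (c + 0.5) * s,
                               grid$origin_y + (r + 0.5) * s)

  # "a beats b" under the species/individuals/observations/index cascade
  beats <- function(a, b) {
    for (k in c("n_species", "n_individuals", "n_obs")) {
      if (a[[k]] != b[[k]]) return(a[[k]] > b[[k]])
    }
    if (a$row != b$row) return(a$row < b$row)
    a$col < b$col
  }
  sort_rank <- function(d) {
    idx <- seq_len(nrow(d))
    for (i in idx) for (j in idx) {
      if (j > i && beats(d[j, ], d[i, ])) {
        tmp <- d[i, ]; d[i, ] <- d[j, ]; d[j, ] <- tmp
      }
    }
    d
  }

  qual <- u[u$n_individuals >= crit$min_individuals &
              u$n_species >= crit$min_species &
              mask$eligible[cbind(u$row + 1, u$col + 1)] &
              !mask$perch[cbind(u$row + 1, u$col + 1)], , drop = FALSE]

  # connected components by iterated label propagation
  if (nrow(qual) > 0) {
    lab <- seq_len(nrow(qual))
    adjacent <- function(i, j) {
      dr <- abs(qual$row[i] - qual$row[j]); dc <- abs(qual$col[i] - qual$col[j])
      if (crit$connectivity == 8) max(dr, dc) == 1 else dr + dc == 1
    }
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(qual))) for (j in seq_len(nrow(qual))) {
        if (i != j && adjacent(i, j) && lab[j] < lab[i]) {
          lab[i] <- lab[j]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    reps <- do.call(rbind, lapply(unique(lab), function(g) {
      m <- qual[lab == g, , drop = FALSE]
      best <- m[1, ]
      for (i in seq_len(nrow(m))) if (beats(m[i, ], best)) best <- m[i, ]
      best
    }))
  } else {
    reps <- qual
  }

  # greedy spacing in rank order
  hs <- list()
  if (nrow(reps) > 0) {
    reps <- sort_rank(reps)
    for (i in seq_len(nrow(reps))) {
      ci <- centroid(reps$row[i], reps$col[i])
      ok <- TRUE
      for (h in hs) {
        ch <- centroid(h$row, h$col)
        if (sqrt(sum((ci - ch)^2)) < crit$min_hotspot_spacing) ok <- FALSE
      }
      if (ok) hs[[length(hs) + 1]] <- reps[i, ]
    }
  }

  # ring scan over every grid cell; azimuth via the (90 - atan2) formulation
  ring_of <- function(hr, hc, radius) {
    ch <- centroid(hr, hc)
    rows <- list()
    for (r in 0:(grid$n_rows - 1)) for (c in 0:(grid$n_cols - 1)) {
      x0 <- grid$origin_x + c * s; x1 <- x0 + s
      y0 <- grid$origin_y + r * s; y1 <- y0 + s
      px <- min(max(ch[1], x0), x1); py <- min(max(ch[2], y0), y1)
      dmin <- sqrt((ch[1] - px)^2 + (ch[2] - py)^2)
      corners <- rbind(c(x0, y0), c(x0, y1), c(x1, y0), c(x1, y1))
      dmax <- max(sqrt((corners[, 1] - ch[1])^2 + (corners[, 2] - ch[2])^2))
      if (dmin <= radius && dmax >= radius) {
        cc <- centroid(r, c)
        az <- (90 - atan2(cc[2] - ch[2], cc[1] - ch[1]) * 180 / pi) %% 360
        rows[[length(rows) + 1]] <- data.frame(
          row = r, col = c, az = az,
          dist = sqrt(sum((cc - ch)^2)))
      }
    }
    if (length(rows) == 0) return(NULL)
    d <- do.call(rbind, rows)
    d[order(d$az, d$dist, d$row, d$col), , drop = FALSE]
  }

  lookup_obs <- function(r, c) {
    hit <- u$row == r & u$col == c
    if (any(hit)) u$n_obs[hit][1] else 0L
  }

  taken <- lapply(hs, function(h) centroid(h$row, h$col))
  pairs <- list(); unpaired <- list()
  for (i in seq_along(hs)) {
    h <- hs[[i]]
    ch <- centroid(h$row, h$col)
    ring <- ring_of(h$row, h$col, crit$control_radius)
    found <- NULL
    if (!is.null(ring)) {
      for (k in seq_len(nrow(ring))) {
        r <- ring$row[k]; c <- ring$col[k]
        if (!mask$farmland[r + 1, c + 1] || mask$perch[r + 1, c + 1]) next
        if (lookup_obs(r, c) > crit$max_control_obs) next
        cc <- centroid(r, c)
        clash <- FALSE
        for (t in taken) {
          if (all(abs(t - ch) < 1e-9)) next  # own hotspot is exempt
          if (sqrt(sum((t - cc)^2)) < crit$min_control_spacing) clash <- TRUE
        }
        if (!clash) {
          found <- data.frame(row = r, col = c, az = ring$az[k])
          break
        }
      }
    }
    if (is.null(found)) {
      unpaired[[length(unpaired) + 1]] <- data.frame(row = h$row, col = h$col)
    } else {
      taken[[length(taken) + 1]] <- centroid(found$row, found$col)
      pairs[[length(pairs) + 1]] <- data.frame(
        hotspot_row = h$row, hotspot_col = h$col,
        control_row = found$row, control_col = found$col,
        azimuth_deg = found$az)
    }
  }
  list(
    pairs = if (length(pairs) > 0) do.call(rbind, pairs) else NULL,
    unpaired = if (length(unpaired) > 0) do.call(rbind, unpaired) else NULL)
}

# ---- logistic regression: grid-search maximum likelihood -------------------

oracle_logistic_ml <- function(x, y) {
  # search on centred x so the intercept and slope axes are near-orthogonal
  # (coordinate-wise grid refinement stalls on a correlated ridge otherwise)
  xbar <- mean(x)
  xc <- x - xbar
  loglik <- function(a0, b1) {
    eta <- a0 + b1 * xc
    sum(y * eta - log(1 + exp(eta)))
  }
  # refine one coordinate by shrinking 1D grids (concave in each coordinate)
  opt1d <- function(f, centre, span = 8) {
    for (i in 1:40) {
      if (span < 1e-8) break
      grid <- seq(centre - span, centre + span, length.out = 81)
      vals <- vapply(grid, f, numeric(1))
      k <- which.max(vals)
      centre <- grid[k]
      if (k > 1 && k < length(grid)) span <- span / 10
    }
    centre
  }
  best <- c(0, 0)
  for (cycle in 1:300) {
    prev <- best
    best[1] <- opt1d(function(b) loglik(b, best[2]), best[1])
    best[2] <- opt1d(function(b) loglik(best[1], b), best[2])
    if (max(abs(best - prev)) < 1e-8) break
  }
  list(beta0 = best[1] - best[2] * xbar, beta = best[2],
       loglik = loglik(best[1], best[2]))
}

oracle_logistic_null_loglik <- function(y) {
  p <- mean(y)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# ---- Wilcoxon: exhaustive permutation enumeration --------------------------

oracle_wilcoxon <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  combs <- utils::combn(n + m, n)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  lo <- mean(ws <= w_obs)
  hi <- mean(ws >= w_obs)
  list(W = w_obs, p = min(1, 2 * min(lo, hi)))
}
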