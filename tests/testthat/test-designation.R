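usage_of <- function(grid, ...) {
  # rows given as list(c(row, col, n_obs, n_ind, n_sp, n_days))
  rows <- list(...)
  d <- as.data.frame(do.call(rbind, rows))
  names(d) <- c("row", "col", "n_obs", "n_individuals", "n_species", "n_days")
  usage_table(d, grid, "test")
}

test_that("cells qualify on individuals and species thresholds", {
  g <- build_grid(c(0, 0, 1000, 1000), 50)
  m <- landcover_mask(g)
  crit <- hotspot_criteria()
  u <- usage_of(g,
                c(2, 2, 6, 3, 2, 3),   # 3 individuals, 2 species: qualifies
                c(5, 5, 9, 3, 1, 3),   # one species: no
                c(8, 8, 4, 2, 2, 2))   # two individuals: no
  q <- qualify_cells(u, m, crit)
  expect_equal(nrow(q), 1)
  expect_equal(c(q$row, q$col), c(2, 2))

  # a qualifying cell on a perch square is rejected with reason "perch"
  perch <- matrix(FALSE, g$n_rows, g$n_cols); perch[3, 3] <- TRUE
  mp <- landcover_mask(g, perch = perch)
  qp <- qualify_cells(u, mp, crit)
  expect_equal(nrow(qp), 0)
  expect_equal(attr(qp, "rejected")$reason, "perch")

  # ineligible landcover removes the candidate silently
  elig <- matrix(TRUE, g$n_rows, g$n_cols); elig[3, 3] <- FALSE
  me <- landcover_mask(g, eligible = elig)
  expect_equal(nrow(qualify_cells(u, me, crit)), 0)
})

test_that("adjacent qualifiers collapse to the best cell of each clump", {
  g <- build_grid(c(0, 0, 1000, 1000), 50)
  crit <- hotspot_criteria()

  # species count rules
  u <- usage_of(g, c(2, 2, 9, 3, 3, 3), c(2, 3, 9, 3, 2, 3))
  r <- resolve_adjacent(as.data.frame(u), crit)
  expect_equal(c(r$row, r$col), c(2, 2))

  # equal species: more individuals wins
  u2 <- usage_of(g, c(2, 2, 9, 3, 2, 3), c(2, 3, 9, 4, 2, 3))
  r2 <- resolve_adjacent(as.data.frame(u2), crit)
  expect_equal(c(r2$row, r2$col), c(2, 3))

  # equal species and individuals: more observations wins
  u3 <- usage_of(g, c(2, 2, 9, 3, 2, 3), c(2, 3, 12, 3, 2, 3))
  r3 <- resolve_adjacent(as.data.frame(u3), crit)
  expect_equal(c(r3$row, r3$col), c(2, 3))

  # full tie: lexicographically smallest cell
  u4 <- usage_of(g, c(2, 3, 9, 3, 2, 3), c(2, 2, 9, 3, 2, 3), c(3, 2, 9, 3, 2, 3))
  r4 <- resolve_adjacent(as.data.frame(u4), crit)
  expect_equal(c(r4$row, r4$col), c(2, 2))
  expect_equal(sort(attr(r4, "rejected")$reason), rep("adjacent", 2))

  # diagonal cells are one clump under queen, two under rook
  u5 <- usage_of(g, c(2, 2, 9, 3, 2, 3), c(3, 3, 9, 3, 3, 3))
  expect_equal(nrow(resolve_adjacent(as.data.frame(u5), crit)), 1)
  crit4 <- hotspot_criteria(connectivity = 4)
  expect_equal(nrow(resolve_adjacent(as.data.frame(u5), crit4)), 2)
})

test_that("hotspot spacing discards competitors strictly closer than 450 m", {
  g <- build_grid(c(0, 0, 2000, 2000), 50)
  crit <- hotspot_criteria()
  # two representatives 400 m apart; the better one (more species) wins
  u <- usage_of(g, c(2, 2, 9, 3, 3, 3), c(2, 10, 9, 3, 2, 3))
  hs <- enforce_spacing(as.data.frame(u), g, crit)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$col, 2)
  expect_equal(attr(hs, "rejected")$reason, "spacing")

  # exactly 450 m apart (9 cells): both kept
  u2 <- usage_of(g, c(2, 2, 9, 3, 3, 3), c(2, 11, 9, 3, 2, 3))
  expect_equal(nrow(enforce_spacing(as.data.frame(u2), g, crit)), 2)
})

test_that("ring cells touch the buffer circle and start due north", {
  g <- build_grid(c(0, 0, 3000, 3000), 50)
  centre <- c(30, 30)
  ring <- ring_cells(centre, g, 500)
  expect_gt(nrow(ring), 0)
  # every centre distance within radius +- half a cell diagonal
  expect_true(all(abs(ring$dist - 500) <= 50 * sqrt(2) / 2 + 1e-9))
  # the first cell contains the point due north at 500 m
  north <- cell_centroid(g, centre[1], centre[2])
  first <- ring[1, ]
  expect_equal(first$col, centre[2])
  expect_equal(first$row, centre[1] + 10)
  expect_equal(first$azimuth_deg, 0)
  # azimuths are non-decreasing (clockwise scan)
  expect_true(all(diff(ring$azimuth_deg) >= 0))

  # a hotspot at the grid corner yields a truncated ring without error
  ring2 <- ring_cells(c(0, 0), g, 500)
  expect_gt(nrow(ring2), 0)
  expect_true(all(ring2$row >= 0 & ring2$col >= 0))
  expect_lt(nrow(ring2), nrow(ring))
})

test_that("control selection walks the ring clockwise with the exclusions", {
  g <- build_grid(c(0, 0, 3000, 3000), 50)
  crit <- hotspot_criteria()
  u <- usage_of(g, c(30, 30, 9, 3, 2, 3))
  m <- landcover_mask(g)
  hs <- enforce_spacing(resolve_adjacent(qualify_cells(u, m, crit), crit), g, crit)

  # unrestricted farmland, zero usage: the due-north cell is chosen
  ctrl <- select_control(hs[1, ], u, m, hs[c("x", "y")], crit)
  expect_equal(c(ctrl$row, ctrl$col), c(40, 30))
  expect_equal(ctrl$azimuth_deg, 0)

  # too many observations at the north cell: next clockwise cell instead
  u2 <- usage_of(g, c(30, 30, 9, 3, 2, 3), c(40, 30, 2, 1, 1, 2))
  ctrl2 <- select_control(hs[1, ], u2, m, hs[c("x", "y")], crit)
  expect_false(all(c(ctrl2$row, ctrl2$col) == c(40, 30)))
  expect_gt(ctrl2$azimuth_deg, 0)
  expect_lt(ctrl2$azimuth_deg, 90)
  # one observation is tolerated
  u3 <- usage_of(g, c(30, 30, 9, 3, 2, 3), c(40, 30, 1, 1, 1, 1))
  ctrl3 <- select_control(hs[1, ], u3, m, hs[c("x", "y")], crit)
  expect_equal(c(ctrl3$row, ctrl3$col), c(40, 30))

  # all ring cells non-farmland: no control
  m2 <- landcover_mask(g, eligible = matrix(TRUE, g$n_rows, g$n_cols),
                       farmland = matrix(FALSE, g$n_rows, g$n_cols))
  expect_null(select_control(hs[1, ], u, m2, hs[c("x", "y")], crit))
})

test_that("full designation pipeline pairs an obvious cluster exactly once", {
  g <- build_grid(c(0, 0, 3000, 3000), 50)
  m <- landcover_mask(g)
  u <- usage_of(g, c(30, 30, 9, 3, 2, 3), c(30, 31, 4, 2, 2, 2))
  res <- designate_sites(u, m)
  expect_s3_class(res, "designation_result")
  expect_equal(nrow(res$pairs), 1)
  expect_equal(c(res$pairs$hotspot_row, res$pairs$hotspot_col), c(30, 30))
  expect_equal(nrow(res$unpaired_hotspots), 0)

  # no qualifying cell: empty result, no error
  u0 <- usage_of(g, c(30, 30, 2, 2, 1, 2))
  expect_message(res0 <- designate_sites(u0, m), "empty")
  expect_equal(nrow(res0$pairs), 0)

  # an exhausted ring leaves the hotspot unpaired
  farm <- matrix(FALSE, g$n_rows, g$n_cols)
  farm[29:33, 29:33] <- TRUE  # farmland only right around the hotspot
  m2 <- landcover_mask(g, eligible = matrix(TRUE, g$n_rows, g$n_cols),
                       farmland = farm)
  res2 <- designate_sites(u, m2)
  expect_equal(nrow(res2$pairs), 0)
  expect_equal(res2$unpaired_hotspots$reason, "ring_exhausted")
})

test_that("designation is deterministic and monotone in min_individuals", {
  for (seed in 1:6) {
    w <- random_world(seed)
    r1 <- suppressMessages(designate_sites(w$usage, w$mask, w$crit))
    r2 <- suppressMessages(designate_sites(w$usage, w$mask, w$crit))
    expect_identical(r1$pairs, r2$pairs)
    expect_identical(r1$unpaired_hotspots, r2$unpaired_hotspots)

    stricter <- w$crit
    stricter$min_individuals <- w$crit$min_individuals + 1
    n_hs_loose <- nrow(r1$pairs) + nrow(r1$unpaired_hotspots)
    r3 <- suppressMessages(designate_sites(w$usage, w$mask, stricter))
    expect_lte(nrow(r3$pairs) + nrow(r3$unpaired_hotspots), n_hs_loose)
  }
})

test_that("designated pairs satisfy the published geometry by construction", {
  w <- random_world(101)
  res <- designate_sites(w$usage, w$mask, w$crit)
  p <- res$pairs
  if (nrow(p) > 0) {
    d <- sqrt((p$hotspot_x - p$control_x)^2 + (p$hotspot_y - p$control_y)^2)
    expect_true(all(abs(d - w$crit$control_radius) <= 50 * sqrt(2) / 2 + 1e-9))
    expect_true(all(p$azimuth_deg >= 0 & p$azimuth_deg < 360))
    # no cell appears twice across all designated sites
    cells <- rbind(p[c("hotspot_row", "hotspot_col")],
                   stats::setNames(p[c("control_row", "control_col")],
                                   c("hotspot_row", "hotspot_col")))
    expect_equal(anyDuplicated(cells), 0)
  }
})
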