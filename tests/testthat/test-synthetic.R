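test_that("landscapes are seed-deterministic with proportions near target", {
  L1 <- generate_landscape(seed = 1)
  L2 <- generate_landscape(seed = 1)
  expect_identical(L1$polygons, L2$polygons)
  expect_identical(L1$patches, L2$patches)
  L3 <- generate_landscape(seed = 2)
  expect_false(identical(L1$patches, L3$patches))

  # realized farmland share stays within +-0.05 of the ~46% target
  expect_gte(L1$realized_props[["farmland"]], 0.41)
  expect_lte(L1$realized_props[["farmland"]], 0.51)
  expect_equal(L1$realized_props[["forest"]], 0.45, tolerance = 0.12)

  # patches sit on farmland, mutually separated
  expect_equal(nrow(L1$patches), 12)
  dd <- as.matrix(stats::dist(L1$patches[c("x", "y")]))
  expect_true(all(dd[upper.tri(dd)] >= 1000))
  cells <- assign_fixes(L1$patches, L1$grid)
  expect_true(all(L1$mask$farmland[cbind(cells$row + 1, cells$col + 1)]))

  # a null world with no patches
  L0 <- generate_landscape(n_patches = 0, seed = 3)
  expect_equal(nrow(L0$patches), 0)

  expect_error(generate_landscape(prop_forest = 0.9), "infeasible")
})

test_that("tracks are reproducible and emit the scheduled number of fixes", {
  w <- small_world(11, alpha = 2)
  t1 <- generate_tracks(w$landscape, w$mcfg)
  t2 <- generate_tracks(w$landscape, w$mcfg)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  expect_equal(length(unique(t1$individual_id)), sum(w$mcfg$n_per_species))
  expect_setequal(unique(t1$species), names(w$mcfg$n_per_species))

  # fixed emission count: one fix per interval across the active window
  days <- as.integer(w$mcfg$season$end_date - w$mcfg$season$start_date) + 1
  active_h <- diff(w$mcfg$active_hours)
  per_ind <- table(t1$individual_id)
  for (sp in names(w$mcfg$n_per_species)) {
    expected <- days * (floor(active_h * 60 / w$mcfg$interval_min[[sp]]) + 1)
    ids <- unique(t1$individual_id[t1$species == sp])
    expect_true(all(per_ind[ids] == expected))
  }

  # changing only the seed changes the output
  mc2 <- w$mcfg
  mc2$seed <- w$mcfg$seed + 1
  t3 <- generate_tracks(w$landscape, mc2)
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))

  expect_error(movement_config(alpha = -1), "alpha")
})

test_that("without attraction, trip destinations are area-proportional", {
  # alpha = 0: destination cells uniform over reachable open cells, so the
  # patch share of foraging trips matches the patch share of open cells
  hits <- 0; trips <- 0; expected <- c()
  for (seed in 1:3) {
    w <- small_world(seed + 40, alpha = 0, n_patches = 3, bbox_side = 2000,
                     days = 10)
    L <- w$landscape
    mc <- w$mcfg
    mc$forage_range <- 5000  # every open cell reachable for every nest
    tr <- generate_tracks(L, mc)
    q <- hotspotr:::prey_intensity(L)
    open_cells <- which(q > 0)
    rc <- arrayInd(open_cells, dim(q)) - 1L
    cen <- cell_centroid(L$grid, rc[, 1], rc[, 2])
    in_patch <- in_any_patch_test(cen$x, cen$y, L$patches)
    expected <- c(expected, mean(in_patch))

    dest <- attr(tr, "dest_cell")
    id <- tr$individual_id
    runs <- rle(paste(id, ifelse(is.na(dest), "nest", dest)))
    vals <- runs$values[!grepl("nest$", runs$values)]
    dcell <- as.integer(sub("^\\S+ ", "", vals))
    patch_cells <- (rc[in_patch, 1]) * L$grid$n_cols + rc[in_patch, 2]
    hits <- hits + sum(dcell %in% patch_cells)
    trips <- trips + length(dcell)
  }
  p_exp <- mean(expected)
  se <- sqrt(p_exp * (1 - p_exp) / trips)
  expect_lt(abs(hits / trips - p_exp), 4 * se + 1e-9)
})

test_that("attraction concentrates designated hotspots on true patches", {
  recall_at <- function(alpha, seeds) {
    mean(sapply(seeds, function(s) {
      w <- small_world(s, alpha = alpha, n_patches = 3, bbox_side = 2500,
                       days = 10)
      u <- tally_usage(resample_tracks(generate_tracks(w$landscape, w$mcfg)),
                       w$landscape$grid, w$mcfg$season)
      res <- designate_sites(u, w$landscape$mask)
      p <- res$pairs
      if (nrow(p) == 0) return(0)
      tt <- ground_truth(w$landscape)
      hit <- sapply(seq_len(nrow(tt)), function(k)
        any(sqrt((p$hotspot_x - tt$x[k])^2 + (p$hotspot_y - tt$y[k])^2) <= 100))
      mean(hit)
    }))
  }
  r0 <- recall_at(0, 61:64)
  r4 <- recall_at(4, 61:64)
  expect_gt(r4, 0.6)
  expect_lte(r0, r4)
})

test_that("surveys respond to the planted enrichment and heterogeneity", {
  L <- generate_landscape(bbox = c(0, 0, 2000, 2000), n_patches = 2, seed = 9)
  sites <- data.frame(
    plot_id = c("h1", "h2", "c1", "c2"),
    kind = c("hotspot", "hotspot", "control", "control"),
    x = c(L$patches$x, L$patches$x + 600),
    y = c(L$patches$y, L$patches$y + 600))
  s1 <- generate_surveys(L, sites, survey_effect_config(seed = 4))
  s2 <- generate_surveys(L, sites, survey_effect_config(seed = 4))
  expect_identical(s1, s2)
  expect_setequal(names(s1), c("birds", "small_mammals", "amphibians", "plants"))
  expect_equal(sort(unique(s1$birds$visit)), 1:2)

  # plant heterogeneity monotonically lowers within-plot similarity
  many <- data.frame(plot_id = sprintf("c%02d", 1:30), kind = "control",
                     x = seq(100, 1900, length.out = 30), y = 100)
  sim_at <- sapply(c(0.15, 0.4, 0.65), function(h) {
    sv <- generate_surveys(generate_landscape(bbox = c(0, 0, 2000, 2000),
                                              n_patches = 0, seed = 9),
                           many, survey_effect_config(plant_het = h, seed = 5))
    tab <- aggregate_surveys(sv["plants"])
    mean(tab$value[tab$predictor == "plant_similarity"])
  })
  expect_true(all(diff(sim_at) < 0))

  # delta = 1 gives identical distributions in and out of patches
  expect_error(survey_effect_config(effect_multiplier = 0.5), "effect_multiplier")
})

test_that("ground truth has one row per patch and survives CSV", {
  L <- generate_landscape(bbox = c(0, 0, 3000, 3000), n_patches = 4, seed = 2)
  tt <- ground_truth(L)
  expect_equal(nrow(tt), 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(tt, f)
  expect_equal(read_ground_truth(f), tt)
  L0 <- generate_landscape(bbox = c(0, 0, 3000, 3000), n_patches = 0, seed = 2)
  expect_equal(nrow(ground_truth(L0)), 0)
})

test_that("the logistic-plot simulator hits its planted slope in large samples", {
  tab <- simulate_logistic_plots(20000, beta = 0.8, seed = 3)
  fit <- fit_binomial_glm(tab, "bird_abundance", standardize = FALSE)
  expect_equal(fit$beta, 0.8, tolerance = 0.05)
})
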