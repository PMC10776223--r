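# Shared fixture builders. Everything is generated in code at test time.

make_tracks <- function(times_min, id = "A1", sp = "A",
                        x = 100, y = 100, day = "2020-04-05") {
  track_set(data.frame(
    individual_id = id, species = sp,
    timestamp = as.POSIXct(paste(day, "00:00:00"), tz = "UTC") + times_min * 60,
    x = x, y = y))
}

# random per-fix records on a grid, skewed so that some cells accumulate
# enough distinct individuals/species to qualify
random_records <- function(nr, nc, n_ind = 6, n_sp = 3, n_fix = 250) {
  sp_of <- paste0("S", sample(n_sp, n_ind, replace = TRUE))
  w <- stats::rexp(nr * nc)^3
  cell <- sample(nr * nc, n_fix, replace = TRUE, prob = w / sum(w))
  ind <- paste0("I", sample(n_ind, n_fix, replace = TRUE))
  data.frame(row = (cell - 1) %/% nc, col = (cell - 1) %% nc,
             ind = ind, sp = sp_of[as.integer(substring(ind, 2))],
             day = sample(10, n_fix, replace = TRUE))
}

# independent tally of records into a usage table (plain loop, no package
# counting code)
usage_from_records <- function(rec, grid, period = "test") {
  cells <- unique(rec[c("row", "col")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    d <- rec[rec$row == cells$row[i] & rec$col == cells$col[i], , drop = FALSE]
    data.frame(row = cells$row[i], col = cells$col[i], n_obs = nrow(d),
               n_individuals = length(unique(d$ind)),
               n_species = length(unique(d$sp)),
               n_days = length(unique(d$day)))
  })
  usage_table(do.call(rbind, rows), grid, period)
}

random_mask <- function(grid, p_elig = 0.85, p_farm = 0.85, p_perch = 0.04) {
  nr <- grid$n_rows; nc <- grid$n_cols
  elig <- matrix(stats::runif(nr * nc) < p_elig, nr, nc)
  farm <- elig & matrix(stats::runif(nr * nc) < p_farm, nr, nc)
  perch <- matrix(stats::runif(nr * nc) < p_perch, nr, nc)
  landcover_mask(grid, eligible = elig, farmland = farm, perch = perch)
}

# independent point-in-patch check (plain loop)
in_any_patch_test <- function(x, y, patches) {
  sapply(seq_along(x), function(i) {
    if (nrow(patches) == 0) return(FALSE)
    any(sqrt((patches$x - x[i])^2 + (patches$y - y[i])^2) <= patches$radius)
  })
}

# one randomized small world for designation-equivalence testing
random_world <- function(seed) {
  set.seed(seed)
  nr <- sample(10:28, 1); nc <- sample(10:28, 1)
  grid <- build_grid(c(0, 0, nc * 50, nr * 50), 50)
  usage <- usage_from_records(
    random_records(nr, nc, n_ind = sample(3:8, 1), n_sp = sample(2:3, 1),
                   n_fix = sample(80:400, 1)), grid)
  crit <- hotspot_criteria(
    min_individuals = sample(2:3, 1), min_species = 2,
    min_hotspot_spacing = sample(c(150, 300, 450), 1),
    control_radius = sample(c(250, 400, 500), 1),
    min_control_spacing = sample(c(300, 500), 1),
    max_control_obs = sample(0:2, 1),
    connectivity = sample(c(4, 8), 1))
  list(grid = grid, usage = usage, mask = random_mask(grid), crit = crit)
}

# small simulated study used by several suites
small_world <- function(seed, alpha = 4, n_patches = 4, bbox_side = 3000,
                        days = 14, year = 2020, delta = 2) {
  L <- generate_landscape(bbox = c(0, 0, bbox_side, bbox_side),
                          n_patches = n_patches, seed = seed)
  mc <- movement_config(
    alpha = alpha, seed = seed + 1000L,
    season = season_window(paste0("spring", year),
                           sprintf("%d-04-01", year),
                           sprintf("%d-04-%02d", year, days)))
  list(landscape = L, mcfg = mc)
}
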