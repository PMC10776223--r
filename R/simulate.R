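# Seed handling: generators take an explicit seed and leave the caller's RNG
# stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic farmland mosaic landscape
#'
#' Produces a desk-scale stand-in for a north-European agricultural study
#' area: a farmland background with non-overlapping rectangular patches of
#' forest, water, peatland and non-farmland open habitat placed to target
#' class proportions (defaults approximate a 45% forested / 55% open mosaic
#' whose open part is mostly farmland, ca 46% of the total area), plus K
#' circular prey-rich patches on farmland - the ground truth that the
#' designation pipeline is later scored against. Patch centres are kept at
#' least `patch_min_sep` apart so designated hotspots are separable.
#'
#' @param bbox study rectangle in metres (default 5 km x 5 km).
#' @param cell_size analysis grid cell in metres (default 50).
#' @param prop_forest,prop_water,prop_peatland,prop_other_open target area
#'   fractions of the subtracted / non-farmland classes; the farmland
#'   background takes the remainder (0.46 by default).
#' @param n_patches number of prey-rich patches (default 12).
#' @param patch_radius patch radius in metres (default 100).
#' @param patch_boost multiplicative prey-intensity factor inside a patch
#'   (> 1; default 5).
#' @param patch_min_sep minimum distance between patch centres (default 1000).
#' @param prop_tol tolerance on realized class proportions (default 0.05).
#' @param seed RNG seed.
#' @return A `landscape` list: `bbox`, `cell_size`, `polygons` (long data
#'   frame `poly_id, class, x, y`), `patches` (`patch_id, x, y, radius,
#'   boost`), `grid`, `mask`, `realized_props`, `seed`.
#' @export
generate_landscape <- function(bbox = c(0, 0, 5000, 5000), cell_size = 50,
                               prop_forest = 0.45, prop_water = 0.01,
                               prop_peatland = 0.035, prop_other_open = 0.045,
                               n_patches = 12, patch_radius = 100,
                               patch_boost = 5, patch_min_sep = 1000,
                               prop_tol = 0.05, seed = 1) {
  bbox <- as_bbox(bbox)
  props <- c(forest = prop_forest, water = prop_water,
             peatland = prop_peatland, other_open = prop_other_open)
  if (any(props < 0) || sum(props) > 0.85) {
    stop("infeasible proportions: non-background classes must sum to <= 0.85")
  }
  stopifnot(patch_radius > 0, patch_boost > 1, n_patches >= 0)
  with_seed(seed, {
    area_tot <- (bbox[3] - bbox[1]) * (bbox[4] - bbox[2])
    rects <- list()
    overlaps <- function(r) {
      if (length(rects) == 0) return(FALSE)
      any(vapply(rects, function(q)
        r[1] < q[3] && q[1] < r[3] && r[2] < q[4] && q[2] < r[4], logical(1)))
    }
    side_range <- list(forest = c(300, 900), water = c(150, 400),
                       peatland = c(150, 500), other_open = c(150, 500))
    polys <- list()
    pid <- 0
    for (cl in names(props)) {
      target <- props[[cl]] * area_tot
      placed <- 0
      fails <- 0
      rng <- side_range[[cl]]
      while (placed < target - 1e-9 && fails < 2000) {
        sx <- stats::runif(1, rng[1], rng[2])
        sy <- stats::runif(1, rng[1], rng[2])
        deficit <- target - placed
        if (sx * sy > deficit) {
          sc <- sqrt(deficit / (sx * sy))
          sx <- max(cell_size, sx * sc)
          sy <- max(cell_size, sy * sc)
        }
        x0 <- stats::runif(1, bbox[1], bbox[3] - sx)
        y0 <- stats::runif(1, bbox[2], bbox[4] - sy)
        r <- c(x0, y0, x0 + sx, y0 + sy)
        if (overlaps(r)) {
          fails <- fails + 1
          if (fails %% 200 == 0) rng <- pmax(cell_size, rng / 1.5)
          next
        }
        rects[[length(rects) + 1]] <- r
        placed <- placed + sx * sy
        pid <- pid + 1
        polys[[pid]] <- data.frame(
          poly_id = sprintf("%s_%03d", cl, pid), class = cl,
          x = c(r[1], r[3], r[3], r[1]), y = c(r[2], r[2], r[4], r[4]))
      }
      if (abs(placed - target) / area_tot > prop_tol) {
        stop("could not realize target proportion for class ", cl)
      }
    }
    polygons <- if (pid > 0) do.call(rbind, polys) else
      data.frame(poly_id = character(), class = character(),
                 x = numeric(), y = numeric())
    grid <- build_grid(bbox, cell_size)
    mask <- rasterize_landcover(grid, polygons, background = "farmland")

    # prey patches on farmland, away from edges, mutually separated
    patches <- data.frame(patch_id = character(), x = numeric(), y = numeric(),
                          radius = numeric(), boost = numeric())
    if (n_patches > 0) {
      idx <- which(mask$farmland, arr.ind = TRUE)
      cen <- cell_centroid(grid, idx[, 1] - 1, idx[, 2] - 1)
      inner <- cen$x >= bbox[1] + patch_radius & cen$x <= bbox[3] - patch_radius &
        cen$y >= bbox[2] + patch_radius & cen$y <= bbox[4] - patch_radius
      cen <- cen[inner, , drop = FALSE]
      ord <- sample(nrow(cen))
      px <- numeric(0); py <- numeric(0)
      for (i in ord) {
        if (length(px) >= n_patches) break
        if (length(px) == 0 ||
            all(sqrt((px - cen$x[i])^2 + (py - cen$y[i])^2) >= patch_min_sep)) {
          px <- c(px, cen$x[i]); py <- c(py, cen$y[i])
        }
      }
      if (length(px) < n_patches) {
        stop("could not place ", n_patches, " patches ", patch_min_sep,
             " m apart on farmland; enlarge the area or reduce n_patches")
      }
      patches <- data.frame(patch_id = sprintf("patch%02d", seq_along(px)),
                            x = px, y = py, radius = patch_radius,
                            boost = patch_boost)
    }

    realized <- c(farmland = mean(mask$class_of == "farmland", na.rm = FALSE))
    for (cl in names(props)) {
      realized[cl] <- mean(!is.na(mask$class_of) & mask$class_of == cl)
    }
    structure(list(bbox = bbox, cell_size = cell_size, polygons = polygons,
                   patches = patches, grid = grid, mask = mask,
                   realized_props = realized, background = "farmland",
                   seed = seed),
              class = "landscape")
  })
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %g x %g m, %d landcover polygon(s), %d prey patch(es)\n",
              x$bbox[3] - x$bbox[1], x$bbox[4] - x$bbox[2],
              length(unique(x$polygons$poly_id)), nrow(x$patches)))
  cat("  realized proportions:",
      paste(sprintf("%s %.2f", names(x$realized_props), x$realized_props),
            collapse = ", "), "\n")
  invisible(x)
}

#' Movement-simulation configuration
#'
#' Defaults emulate the telemetry structure of a multi-species raptor study:
#' four species with species-dependent fix intervals (extensively flying,
#' well-charging species at 5-10 min; perching species at 10-60 min) and a
#' handful of tracked individuals per species. Individuals are central-place
#' foragers: they alternate nest residence with foraging trips whose
#' destination cell is drawn with probability proportional to prey intensity
#' raised to the attraction exponent `alpha` (`alpha = 0`: no attraction,
#' destinations uniform over reachable open cells).
#'
#' @param n_per_species named integer vector of individuals per species.
#' @param interval_min named numeric vector of fix intervals (minutes) per
#'   species; names must match `n_per_species`.
#' @param season a [season_window()] of the simulated tracking period.
#' @param alpha attraction exponent (>= 0, default 2).
#' @param forage_range maximum nest-to-destination distance, metres.
#' @param wander_sd within-trip positional spread around the destination
#'   centroid, metres.
#' @param gps_noise_sd GPS positional error SD, metres (default 10).
#' @param active_hours daily activity window `c(start_hour, end_hour)`.
#' @param nest_stay_min range (minutes) of nest bouts between trips.
#' @param trip_min range (minutes) of foraging-trip durations.
#' @param jitter_s uniform emission-time jitter, seconds.
#' @param seed RNG seed.
#' @return A `movement_config` list.
#' @export
movement_config <- function(n_per_species = c(LSE = 3, WMH = 4, CB = 4, NGH = 5),
                            interval_min = c(LSE = 8, WMH = 5, CB = 15, NGH = 30),
                            season = season_window("spring2020", "2020-04-01",
                                                   "2020-05-31"),
                            alpha = 2, forage_range = 3000, wander_sd = 50,
                            gps_noise_sd = 10, active_hours = c(6, 20),
                            nest_stay_min = c(15, 90), trip_min = c(30, 120),
                            jitter_s = 30, seed = 1) {
  if (alpha < 0) stop("alpha must be >= 0")
  stopifnot(all(names(n_per_species) %in% names(interval_min)),
            all(interval_min > 0), all(n_per_species >= 0),
            all(nest_stay_min > 0), all(trip_min > 0),
            active_hours[1] < active_hours[2])
  structure(as.list(environment()), class = "movement_config")
}

prey_intensity <- function(landscape) {
  grid <- landscape$grid
  q <- matrix(0, grid$n_rows, grid$n_cols)
  q[landscape$mask$eligible] <- 1
  if (nrow(landscape$patches) > 0) {
    idx <- which(q > 0, arr.ind = TRUE)
    cen <- cell_centroid(grid, idx[, 1] - 1, idx[, 2] - 1)
    for (k in seq_len(nrow(landscape$patches))) {
      p <- landscape$patches[k, ]
      inpatch <- (cen$x - p$x)^2 + (cen$y - p$y)^2 <= p$radius^2
      q[idx[inpatch, , drop = FALSE]] <- q[idx[inpatch, , drop = FALSE]] * p$boost
    }
  }
  q
}

#' Simulate multi-individual raptor tracks over a landscape
#'
#' Each individual nests at a random farmland cell and alternates nest bouts
#' with foraging trips; every trip's destination cell is drawn from the open
#' cells within `forage_range` of the nest with probability proportional to
#' `intensity^alpha`, where intensity is 1 on open land and `boost`-fold
#' inside prey patches. Fixes are emitted at the species fix interval (plus
#' jitter) during the daily activity window; positions are the nest or a
#' Gaussian wander around the trip destination centroid, plus GPS noise, and
#' are clamped to the study rectangle.
#'
#' @param landscape a [generate_landscape()] result.
#' @param cfg a [movement_config()].
#' @return A [track_set()]; attributes `state` (character,
#'   `"nest"`/`"forage"` per fix) and `dest_cell` (0-based `row * n_cols +
#'   col` of the trip destination, NA for nest fixes) expose the generative
#'   ground truth for validation.
#' @export
generate_tracks <- function(landscape, cfg = movement_config()) {
  stopifnot(inherits(cfg, "movement_config"))
  grid <- landscape$grid
  q <- prey_intensity(landscape)
  w_all <- ifelse(q > 0, q^cfg$alpha, 0)
  cell_idx <- which(w_all > 0)
  cell_rc <- arrayInd(cell_idx, dim(w_all)) - 1L
  cen <- cell_centroid(grid, cell_rc[, 1], cell_rc[, 2])
  farm_idx <- which(landscape$mask$farmland)

  days <- seq(cfg$season$start_date, cfg$season$end_date, by = "day")
  day0 <- as.POSIXct(paste0(format(days), " 00:00:00"), tz = "UTC")
  t_act0 <- cfg$active_hours[1] * 3600
  t_act1 <- cfg$active_hours[2] * 3600

  with_seed(cfg$seed, {
    out <- list()
    states <- list()
    dests <- list()
    for (sp in names(cfg$n_per_species)) {
      n_ind <- cfg$n_per_species[[sp]]
      step <- cfg$interval_min[[sp]] * 60
      for (ii in seq_len(n_ind)) {
        id <- sprintf("%s%02d", sp, ii)
        nest_cell <- farm_idx[sample.int(length(farm_idx), 1)]
        nrc <- arrayInd(nest_cell, dim(w_all)) - 1L
        nest <- cell_centroid(grid, nrc[1], nrc[2])
        reach <- (cen$x - nest$x)^2 + (cen$y - nest$y)^2 <= cfg$forage_range^2
        ridx <- which(reach)
        if (length(ridx) == 0) ridx <- seq_along(cell_idx)
        rw <- w_all[cell_idx[ridx]]

        # foraging-trip schedule across the season (seconds from season start)
        trip_s <- numeric(0); trip_e <- numeric(0); trip_d <- integer(0)
        for (di in seq_along(days)) {
          base <- as.numeric(day0[di])
          t <- base + t_act0 + stats::runif(1, cfg$nest_stay_min[1],
                                            cfg$nest_stay_min[2]) * 60
          while (t + cfg$trip_min[1] * 60 < base + t_act1) {
            dur <- stats::runif(1, cfg$trip_min[1], cfg$trip_min[2]) * 60
            trip_s <- c(trip_s, t)
            trip_e <- c(trip_e, min(t + dur, base + t_act1))
            trip_d <- c(trip_d, ridx[sample.int(length(ridx), 1,
                                                prob = rw / sum(rw))])
            t <- trip_e[length(trip_e)] +
              stats::runif(1, cfg$nest_stay_min[1], cfg$nest_stay_min[2]) * 60
          }
        }

        # emission times over all days
        per_day <- lapply(seq_along(days), function(di) {
          tt <- seq(as.numeric(day0[di]) + t_act0,
                    as.numeric(day0[di]) + t_act1, by = step)
          tt + stats::runif(length(tt), -cfg$jitter_s, cfg$jitter_s)
        })
        tt <- unlist(per_day)
        seg <- findInterval(tt, trip_s)
        on_trip <- seg > 0 & tt < trip_e[pmax(seg, 1)]
        dest <- ifelse(on_trip, trip_d[pmax(seg, 1)], NA_integer_)

        x <- rep(nest$x, length(tt))
        y <- rep(nest$y, length(tt))
        f <- which(on_trip)
        if (length(f) > 0) {
          x[f] <- cen$x[dest[f]] + stats::rnorm(length(f), 0, cfg$wander_sd)
          y[f] <- cen$y[dest[f]] + stats::rnorm(length(f), 0, cfg$wander_sd)
        }
        x <- x + stats::rnorm(length(tt), 0, cfg$gps_noise_sd)
        y <- y + stats::rnorm(length(tt), 0, cfg$gps_noise_sd)
        eps <- 1e-6
        x <- pmin(pmax(x, landscape$bbox[1]), landscape$bbox[3] - eps)
        y <- pmin(pmax(y, landscape$bbox[2]), landscape$bbox[4] - eps)

        out[[id]] <- data.frame(
          individual_id = id, species = sp,
          timestamp = as.POSIXct(tt, origin = "1970-01-01", tz = "UTC"),
          x = x, y = y)
        states[[id]] <- ifelse(on_trip, "forage", "nest")
        dests[[id]] <- ifelse(is.na(dest), NA_integer_,
                              cell_rc[dest, 1] * grid$n_cols + cell_rc[dest, 2])
      }
    }
    d <- do.call(rbind, out)
    ts <- track_set(d, crs_id = "simulated-metric")
    if (nrow(ts) == nrow(d)) {
      attr(ts, "state") <- unlist(states, use.names = FALSE)
      attr(ts, "dest_cell") <- unlist(dests, use.names = FALSE)
    }
    ts
  })
}

#' Survey-simulation configuration
#'
#' Controls the biodiversity surveys generated at designated sites. Fauna
#' counts are negative binomial (overdispersed, the field norm) with mean
#' `baseline * effect_multiplier` inside prey patches and `baseline` outside;
#' species identities are drawn from regional pools with geometrically
#' decaying relative abundances, so richness rises with local abundance.
#' Plant plots get a local species pool (larger inside patches) sampled into
#' five quadrats with per-quadrat omission probability `plant_het`
#' (heterogeneity): higher heterogeneity means more compositional turnover
#' between quadrats and hence a lower mean pairwise Jaccard index; inside
#' patches heterogeneity is raised with the effect multiplier.
#'
#' @param baselines named list of mean counts at control conditions.
#' @param effect_multiplier delta applied inside prey patches (1 = null,
#'   default 2).
#' @param pools named list of regional species-pool sizes.
#' @param dispersion negative-binomial size parameter (default 5).
#' @param plant_het baseline quadrat omission probability in `(0, 1)`.
#' @param n_quadrats quadrats per plant plot (default 5).
#' @param n_visits bird point-count visits (default 2).
#' @param seed RNG seed.
#' @return A `survey_effect_config` list.
#' @export
survey_effect_config <- function(baselines = list(birds = 8, mammals = 5,
                                                  amphibians = 5),
                                 effect_multiplier = 2,
                                 pools = list(birds = 25, mammals = 9,
                                              amphibians = 7, plants = 30),
                                 dispersion = 5, plant_het = 0.35,
                                 n_quadrats = 5, n_visits = 2, seed = 1) {
  if (effect_multiplier < 1) stop("effect_multiplier must be >= 1 (1 = null)")
  stopifnot(plant_het > 0, plant_het < 1, dispersion > 0, n_quadrats >= 2)
  structure(as.list(environment()), class = "survey_effect_config")
}

in_any_patch <- function(x, y, patches) {
  if (nrow(patches) == 0) return(rep(FALSE, length(x)))
  hit <- rep(FALSE, length(x))
  for (k in seq_len(nrow(patches))) {
    hit <- hit | ((x - patches$x[k])^2 + (y - patches$y[k])^2 <=
                    patches$radius[k]^2)
  }
  hit
}

geom_pool_probs <- function(size, theta = 0.8) {
  p <- theta^(seq_len(size) - 1)
  p / sum(p)
}

draw_community <- function(mu, size, pool, prefix) {
  n <- stats::rnbinom(1, mu = mu, size = size)
  if (n == 0) {
    return(data.frame(species = paste0(prefix, "none"), count = 0))
  }
  sp <- sample(paste0(prefix, seq_len(pool)), n, replace = TRUE,
               prob = geom_pool_probs(pool))
  tab <- table(sp)
  data.frame(species = names(tab), count = as.integer(tab))
}

#' Simulate biodiversity surveys at designated sites
#'
#' @param landscape a [generate_landscape()] result (supplies the prey-patch
#'   ground truth that drives the enrichment effect).
#' @param sites data frame with `plot_id`, `kind` (`"hotspot"`/`"control"`),
#'   `x`, `y` - e.g. [pairs_to_sites()] of a designation.
#' @param cfg a [survey_effect_config()].
#' @return named list of raw survey tables (`birds`, `small_mammals`,
#'   `amphibians`, `plants`) in the schemas of [aggregate_surveys()].
#' @export
generate_surveys <- function(landscape, sites, cfg = survey_effect_config()) {
  stopifnot(inherits(cfg, "survey_effect_config"))
  sites <- as.data.frame(sites)
  stopifnot(all(c("plot_id", "kind", "x", "y") %in% names(sites)))
  site_class <- ifelse(sites$kind == "hotspot", 1L, 0L)
  enriched <- in_any_patch(sites$x, sites$y, landscape$patches)
  mult <- ifelse(enriched, cfg$effect_multiplier, 1)

  with_seed(cfg$seed, {
    birds <- list(); mams <- list(); amph <- list(); plants <- list()
    for (i in seq_len(nrow(sites))) {
      p <- sites$plot_id[i]
      for (v in seq_len(cfg$n_visits)) {
        com <- draw_community(cfg$baselines$birds * mult[i], cfg$dispersion,
                              cfg$pools$birds, "b")
        birds[[length(birds) + 1]] <- data.frame(
          plot_id = p, site_class = site_class[i], visit = v,
          abundance = sum(com$count),
          richness = sum(com$count > 0))
      }
      com <- draw_community(cfg$baselines$mammals * mult[i], cfg$dispersion,
                            cfg$pools$mammals, "m")
      mams[[length(mams) + 1]] <- data.frame(
        plot_id = p, site_class = site_class[i],
        species = com$species, count = com$count)
      com <- draw_community(cfg$baselines$amphibians * mult[i], cfg$dispersion,
                            cfg$pools$amphibians, "a")
      amph[[length(amph) + 1]] <- data.frame(
        plot_id = p, site_class = site_class[i],
        species = com$species, count = com$count)

      het <- if (enriched[i]) {
        1 - (1 - cfg$plant_het) * cfg$effect_multiplier^(-0.3)
      } else cfg$plant_het
      # local pool size varies between plots (Poisson about the configured
      # mean, larger inside patches), as in real vegetation mosaics
      pool_mu <- cfg$pools$plants *
        (if (enriched[i]) cfg$effect_multiplier^0.4 else 1)
      pool_n <- min(3 * cfg$pools$plants, max(3, stats::rpois(1, pool_mu)))
      local_pool <- sample(paste0("p", seq_len(cfg$pools$plants * 3)), pool_n)
      for (qd in seq_len(cfg$n_quadrats)) {
        present <- local_pool[stats::runif(pool_n) > het]
        if (length(present) > 0) {
          plants[[length(plants) + 1]] <- data.frame(
            plot_id = p, site_class = site_class[i], quadrat = qd,
            species = present)
        }
      }
    }
    list(birds = do.call(rbind, birds),
         small_mammals = do.call(rbind, mams),
         amphibians = do.call(rbind, amph),
         plants = do.call(rbind, plants))
  })
}

#' Ground-truth prey-patch table
#'
#' @param landscape a [generate_landscape()] result.
#' @return data frame `patch_id, x, y, radius, boost` (one row per patch) for
#'   scoring designation recall/precision against the simulation truth.
#' @export
ground_truth <- function(landscape) {
  landscape$patches
}

#' @rdname ground_truth
#' @param truth a ground-truth table.
#' @param path CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname ground_truth
#' @export
read_ground_truth <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$patch_id <- as.character(d$patch_id)
  d
}

#' Simulate a predictor table with a known logistic effect
#'
#' Direct generator for calibration studies of the GLM stage: a standard
#' normal predictor and site classes drawn from
#' `P(hotspot) = plogis(beta0 + beta * x)`.
#'
#' @param n number of plots.
#' @param beta true log-odds slope.
#' @param beta0 true intercept (default 0: balanced classes).
#' @param predictor predictor name for the table (default
#'   `"bird_abundance"`).
#' @param seed RNG seed.
#' @return predictor table as in [aggregate_surveys()].
#' @export
simulate_logistic_plots <- function(n, beta, beta0 = 0,
                                    predictor = "bird_abundance", seed = NULL) {
  with_seed(seed, {
    x <- stats::rnorm(n)
    y <- stats::rbinom(n, 1, stats::plogis(beta0 + beta * x))
    data.frame(plot_id = sprintf("plot%03d", seq_len(n)), site_class = y,
               predictor = predictor, value = x)
  })
}
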