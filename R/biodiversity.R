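#' Jaccard similarity of two species sets
#'
#' `|intersect| / |union|`. Two empty sets are taken as identical composition
#' (similarity 1); comparisons involving empty quadrats are therefore
#' meaningful but worth auditing in sparse vegetation data.
#'
#' @param a,b character vectors of species codes (duplicates ignored).
#' @return similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Mean pairwise Jaccard similarity across quadrats
#'
#' The plant-diversity measure of a 50 m plot: species lists of the five 1 m2
#' quadrats are compared in all unordered pairs (10 pairs for 5 quadrats) and
#' the Jaccard indices averaged. Lower values mean greater compositional
#' turnover between quadrats, i.e. higher within-plot diversity.
#'
#' @param quadrats list of >= 2 species-code vectors.
#' @return mean similarity in `[0, 1]`.
#' @export
mean_pairwise_jaccard <- function(quadrats) {
  if (!is.list(quadrats) || length(quadrats) < 2) {
    stop("need at least 2 quadrats")
  }
  pairs <- utils::combn(length(quadrats), 2)
  mean(apply(pairs, 2, function(ij) jaccard(quadrats[[ij[1]]], quadrats[[ij[2]]])))
}

#' Plot-level species richness across quadrats
#'
#' @param quadrats list of >= 1 species-code vectors.
#' @return count of distinct species in the union of all quadrat lists.
#' @export
plot_richness <- function(quadrats) {
  if (!is.list(quadrats) || length(quadrats) < 1) stop("need at least 1 quadrat")
  length(unique(unlist(lapply(quadrats, as.character))))
}

#' The eight hotspot-vs-control predictors
#'
#' @return character vector of canonical predictor names.
#' @export
predictor_names <- function() {
  c("bird_abundance", "bird_richness", "mammal_abundance", "mammal_richness",
    "amphibian_abundance", "amphibian_richness", "plant_similarity",
    "plant_richness")
}

#' Aggregate raw survey tables into the per-plot predictor table
#'
#' Taxon-group schemas (all CSV-friendly long data frames; `site_class` is 1
#' for hotspot plots, 0 for controls):
#' * `birds`: `plot_id, site_class, visit, abundance, richness` - one row per
#'   point-count visit (two per season); abundance and richness are averaged
#'   over the visits. A plot with a number of visits other than two is used
#'   as-is with a warning.
#' * `small_mammals`: `plot_id, site_class, species, count` - trap captures
#'   summed to abundance; distinct captured species to richness.
#' * `amphibians`: `plot_id, site_class, species, count` - transect counts
#'   summed to abundance; distinct species to richness.
#' * `plants`: `plot_id, site_class, quadrat, species` - one row per species
#'   per 1 m2 quadrat; yields `plant_richness` (union over quadrats) and
#'   `plant_similarity` (mean pairwise Jaccard). A plot with fewer than two
#'   quadrats is an error.
#'
#' @param surveys named list with any of `birds`, `small_mammals`,
#'   `amphibians`, `plants` (missing groups are simply absent from the
#'   output).
#' @return A predictor table: data frame `plot_id, site_class, predictor,
#'   value`, one row per plot per available predictor.
#' @export
aggregate_surveys <- function(surveys) {
  out <- list()
  add <- function(plot_id, site_class, predictor, value) {
    out[[length(out) + 1]] <<- data.frame(
      plot_id = as.character(plot_id), site_class = as.integer(site_class),
      predictor = predictor, value = as.numeric(value))
  }

  if (!is.null(surveys$birds)) {
    b <- surveys$birds
    for (p in unique(b$plot_id)) {
      d <- b[b$plot_id == p, , drop = FALSE]
      if (length(unique(d$visit)) != 2) {
        warning("bird plot ", p, " has ", length(unique(d$visit)),
                " visit(s) instead of 2; averaging what is available")
      }
      add(p, d$site_class[1], "bird_abundance", mean(d$abundance))
      add(p, d$site_class[1], "bird_richness", mean(d$richness))
    }
  }
  count_group <- function(d, prefix) {
    for (p in unique(d$plot_id)) {
      dd <- d[d$plot_id == p, , drop = FALSE]
      add(p, dd$site_class[1], paste0(prefix, "_abundance"), sum(dd$count))
      add(p, dd$site_class[1], paste0(prefix, "_richness"),
          length(unique(dd$species[dd$count > 0])))
    }
  }
  if (!is.null(surveys$small_mammals)) count_group(surveys$small_mammals, "mammal")
  if (!is.null(surveys$amphibians)) count_group(surveys$amphibians, "amphibian")
  if (!is.null(surveys$plants)) {
    pl <- surveys$plants
    for (p in unique(pl$plot_id)) {
      d <- pl[pl$plot_id == p, , drop = FALSE]
      quads <- split(d$species, d$quadrat)
      if (length(quads) < 2) {
        stop("plant plot ", p, " has fewer than 2 quadrats")
      }
      add(p, d$site_class[1], "plant_richness", plot_richness(quads))
      add(p, d$site_class[1], "plant_similarity", mean_pairwise_jaccard(quads))
    }
  }
  if (length(out) == 0) {
    return(data.frame(plot_id = character(), site_class = integer(),
                      predictor = character(), value = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit one single-predictor binomial GLM (hotspot vs control)
#'
#' Logistic regression of site class (hotspot = 1, control = 0) on a single
#' survey predictor, fitted by iteratively reweighted least squares
#' (relative tolerance 1e-10). The predictor is z-scored by default so slopes
#' are comparable across predictors; Wald 95% confidence interval and p-value
#' are reported along with AIC, McFadden's R2 and Nagelkerke's pseudo R2.
#'
#' @param table a predictor table from [aggregate_surveys()].
#' @param predictor one of [predictor_names()] present in `table`.
#' @param standardize z-score the predictor before fitting (default TRUE).
#' @return one-row data frame: `predictor, beta, beta0, ci_low, ci_high,
#'   p_value, n, mcfadden_r2, nagelkerke_r2, aic, converged`.
#' @export
fit_binomial_glm <- function(table, predictor, standardize = TRUE) {
  d <- table[table$predictor == predictor & is.finite(table$value), , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for predictor ", predictor)
  y <- d$site_class
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least 2 plots in each class for ", predictor)
  }
  x <- d$value
  if (stats::sd(x) == 0) stop("degenerate predictor (constant): ", predictor)
  if (standardize) x <- (x - mean(x)) / stats::sd(x)

  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  converged <- fit$converged && !separation
  if (!converged) {
    warning("model for ", predictor, " flagged non-converged (separation?)")
  }
  sm <- summary(fit)$coefficients
  beta <- sm["x", "Estimate"]
  se <- sm["x", "Std. Error"]
  z975 <- stats::qnorm(0.975)
  ll_model <- as.numeric(stats::logLik(fit))
  null_fit <- stats::glm(y ~ 1, family = stats::binomial(),
                         control = stats::glm.control(epsilon = 1e-10))
  ll_null <- as.numeric(stats::logLik(null_fit))
  data.frame(
    predictor = predictor,
    beta = beta, beta0 = sm["(Intercept)", "Estimate"],
    ci_low = beta - z975 * se, ci_high = beta + z975 * se,
    p_value = sm["x", "Pr(>|z|)"], n = length(y),
    mcfadden_r2 = mcfadden_r2(ll_model, ll_null),
    nagelkerke_r2 = nagelkerke_r2(ll_model, ll_null, length(y)),
    aic = fit$aic, converged = converged
  )
}

#' McFadden's R2
#'
#' `1 - logLik(model) / logLik(null)` for a likelihood-based model and its
#' intercept-only null fitted on the same rows.
#'
#' @param ll_model,ll_null log-likelihoods.
#' @return value in `[0, 1)`.
#' @export
mcfadden_r2 <- function(ll_model, ll_null) {
  if (ll_null == 0) stop("degenerate outcome: null log-likelihood is 0")
  1 - ll_model / ll_null
}

#' Nagelkerke's pseudo R2
#'
#' Cox-Snell R2 rescaled to a maximum of 1:
#' `(1 - exp(2 (ll_null - ll_model) / n)) / (1 - exp(2 ll_null / n))`.
#'
#' @param ll_model,ll_null log-likelihoods.
#' @param n number of observations.
#' @return value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(ll_model, ll_null, n) {
  if (n <= 0) stop("n must be positive")
  if (ll_null == 0) stop("degenerate outcome: null log-likelihood is 0")
  (1 - exp(2 * (ll_null - ll_model) / n)) / (1 - exp(2 * ll_null / n))
}

#' Run the full set of single-predictor models
#'
#' One binomial GLM per predictor available in the table (up to the eight
#' canonical ones), each fitted on that predictor's non-missing plots, so `n`
#' varies across rows exactly as the survey coverage does.
#'
#' @inheritParams fit_binomial_glm
#' @return data frame with one [fit_binomial_glm()] row per predictor.
#' @export
run_table1 <- function(table, standardize = TRUE) {
  have <- intersect(predictor_names(), unique(table$predictor))
  if (length(have) == 0) stop("no known predictors in table")
  missing_preds <- setdiff(predictor_names(), have)
  if (length(missing_preds) > 0) {
    message("predictor(s) absent from table: ",
            paste(missing_preds, collapse = ", "))
  }
  res <- do.call(rbind, lapply(have, function(p)
    fit_binomial_glm(table, p, standardize = standardize)))
  rownames(res) <- NULL
  res
}
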