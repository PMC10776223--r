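test_that("Jaccard similarity follows the set definition", {
  expect_equal(jaccard(c("x", "y"), c("y", "z")), 1 / 3)
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(character(0), character(0)), 1)
  expect_equal(jaccard(c("a"), character(0)), 0)
  # symmetry and duplicates
  expect_equal(jaccard(c("a", "a", "b"), c("b", "c")),
               jaccard(c("b", "c"), c("a", "b")))
})

test_that("mean pairwise Jaccard averages all unordered quadrat pairs", {
  expect_equal(mean_pairwise_jaccard(rep(list(c("a", "b")), 5)), 1)
  disjoint <- list("a", "b", "c", "d", "e")
  expect_equal(mean_pairwise_jaccard(disjoint), 0)

  quads <- list(c("a", "b"), c("b", "c"), "c", c("a", "b", "c"), "b")
  # independent enumeration of the 10 pair similarities
  expected <- local({
    jac <- function(p, q) {
      if (length(union(p, q)) == 0) return(1)
      sum(p %in% q) * 0 + length(intersect(p, q)) / length(union(p, q))
    }
    vals <- c()
    for (i in 1:4) for (j in (i + 1):5) vals <- c(vals, jac(quads[[i]], quads[[j]]))
    mean(vals)
  })
  expect_equal(mean_pairwise_jaccard(quads), expected)
  # order invariance
  expect_equal(mean_pairwise_jaccard(quads[c(3, 5, 1, 4, 2)]), expected)
  expect_error(mean_pairwise_jaccard(list("a")), "2 quadrats")
})

test_that("plot richness is the union of quadrat lists", {
  expect_equal(plot_richness(list(c("a", "b"), c("b", "c"))), 3)
  expect_equal(plot_richness(list(character(0), character(0))), 0)
  expect_equal(plot_richness(list("a")), 1)
})

test_that("survey aggregation follows the per-taxon protocols", {
  surveys <- list(
    birds = data.frame(plot_id = rep("p1", 2), site_class = 1, visit = 1:2,
                       abundance = c(4, 6), richness = c(3, 5)),
    small_mammals = data.frame(plot_id = "p1", site_class = 1,
                               species = c("v", "s", "v"), count = c(2, 1, 0)),
    amphibians = data.frame(plot_id = "p1", site_class = 1,
                            species = c("rt", "bb"), count = c(3, 1)),
    plants = data.frame(plot_id = "p1", site_class = 1,
                        quadrat = rep(1:5, each = 7),
                        species = rep(paste0("sp", 1:7), 5)))
  tab <- aggregate_surveys(surveys)
  val <- function(p) tab$value[tab$predictor == p]
  expect_equal(val("bird_abundance"), 5)
  expect_equal(val("bird_richness"), 4)
  expect_equal(val("mammal_abundance"), 3)
  expect_equal(val("mammal_richness"), 2)   # v and s; the zero-count row ignored
  expect_equal(val("amphibian_abundance"), 4)
  expect_equal(val("amphibian_richness"), 2)
  expect_equal(val("plant_richness"), 7)
  expect_equal(val("plant_similarity"), 1)
  expect_equal(nrow(tab), 8)

  # one bird visit: used with a warning
  one_visit <- list(birds = data.frame(plot_id = "p2", site_class = 0, visit = 1,
                                       abundance = 2, richness = 2))
  expect_warning(t2 <- aggregate_surveys(one_visit), "visit")
  expect_equal(t2$value[t2$predictor == "bird_abundance"], 2)

  # a plant plot with fewer than two quadrats is an error
  expect_error(aggregate_surveys(list(
    plants = data.frame(plot_id = "p3", site_class = 0, quadrat = 1,
                        species = "sp1"))), "quadrats")
})

toy_table <- function() {
  # 8 plots, mild separation
  data.frame(plot_id = paste0("p", 1:8),
             site_class = c(1, 1, 1, 1, 0, 0, 0, 0),
             predictor = "bird_abundance",
             value = c(6, 9, 4, 8, 3, 5, 2, 6))
}

test_that("the logistic slope matches a grid-search ML oracle to 1e-4", {
  tab <- toy_table()
  fit <- fit_binomial_glm(tab, "bird_abundance", standardize = FALSE)
  o <- oracle_logistic_ml(tab$value, tab$site_class)
  expect_equal(fit$beta, o$beta, tolerance = 1e-4)
  expect_equal(fit$beta0, o$beta0, tolerance = 1e-3)

  # and with the standardized predictor
  fit_z <- fit_binomial_glm(tab, "bird_abundance", standardize = TRUE)
  z <- (tab$value - mean(tab$value)) / sd(tab$value)
  oz <- oracle_logistic_ml(z, tab$site_class)
  expect_equal(fit_z$beta, oz$beta, tolerance = 1e-4)
})

test_that("pseudo R-squared statistics match oracle likelihoods", {
  tab <- toy_table()
  fit <- fit_binomial_glm(tab, "bird_abundance", standardize = FALSE)
  o <- oracle_logistic_ml(tab$value, tab$site_class)
  ll0 <- oracle_logistic_null_loglik(tab$site_class)
  n <- nrow(tab)
  expect_equal(fit$mcfadden_r2, 1 - o$loglik / ll0, tolerance = 1e-6)
  expect_equal(fit$nagelkerke_r2,
               (1 - exp(2 * (ll0 - o$loglik) / n)) / (1 - exp(2 * ll0 / n)),
               tolerance = 1e-6)
  expect_equal(fit$aic, 2 * 2 - 2 * o$loglik, tolerance = 1e-6)

  # arithmetic contracts
  expect_equal(mcfadden_r2(-10, -10), 0)
  expect_equal(mcfadden_r2(-5, -10), 0.5)
  expect_error(mcfadden_r2(-1, 0), "degenerate")
  expect_equal(nagelkerke_r2(-10, -10, 20), 0)
  # perfect prediction of a balanced outcome approaches 1
  expect_equal(nagelkerke_r2(0, 100 * log(0.5), 100), 1)
})

test_that("a class-symmetric predictor yields a null slope", {
  tab <- data.frame(plot_id = paste0("p", 1:8),
                    site_class = rep(c(1, 0), each = 4),
                    predictor = "bird_abundance",
                    value = rep(c(1, 2, 3, 4), 2))
  fit <- fit_binomial_glm(tab, "bird_abundance")
  expect_equal(fit$beta, 0, tolerance = 1e-8)
  expect_equal(fit$p_value, 1, tolerance = 1e-6)
  expect_true(fit$ci_low <= 0 && fit$ci_high >= 0)
})

test_that("flipping class labels mirrors the slope and preserves fit", {
  tab <- toy_table()
  f1 <- fit_binomial_glm(tab, "bird_abundance")
  tab2 <- tab
  tab2$site_class <- 1 - tab2$site_class
  f2 <- fit_binomial_glm(tab2, "bird_abundance")
  expect_equal(f2$beta, -f1$beta, tolerance = 1e-8)
  expect_equal(f2$aic, f1$aic, tolerance = 1e-8)
  expect_equal(f2$mcfadden_r2, f1$mcfadden_r2, tolerance = 1e-8)
  expect_equal(f2$nagelkerke_r2, f1$nagelkerke_r2, tolerance = 1e-8)
  expect_equal(f2$p_value, f1$p_value, tolerance = 1e-8)
})

test_that("degenerate model inputs raise the documented errors", {
  tab <- toy_table()
  tab$value <- 5
  expect_error(fit_binomial_glm(tab, "bird_abundance"), "degenerate predictor")
  small <- toy_table()[c(1, 5, 6, 7, 8), ]
  expect_error(fit_binomial_glm(small, "bird_abundance"), "2 plots in each class")
  expect_error(fit_binomial_glm(toy_table(), "plant_richness"), "no rows")
})

test_that("pseudo R-squared grows with class separation", {
  sep_r2 <- sapply(c(0.5, 1.5, 3), function(shift) {
    tab <- data.frame(plot_id = paste0("p", 1:40),
                      site_class = rep(c(0, 1), each = 20),
                      predictor = "bird_abundance",
                      value = c(seq(0, 2, length.out = 20),
                                seq(0, 2, length.out = 20) + shift))
    fit <- suppressWarnings(fit_binomial_glm(tab, "bird_abundance"))
    c(fit$mcfadden_r2, fit$nagelkerke_r2)
  })
  expect_true(all(diff(sep_r2[1, ]) > 0))
  expect_true(all(diff(sep_r2[2, ]) > 0))
})

test_that("run_table1 fits one model per available predictor", {
  set.seed(42)
  tabs <- lapply(predictor_names(), function(p)
    data.frame(plot_id = paste0("p", 1:30), site_class = rep(c(1, 0), 15),
               predictor = p, value = rnorm(30)))
  full <- do.call(rbind, tabs)
  res <- run_table1(full)
  expect_equal(nrow(res), 8)
  expect_setequal(res$predictor, predictor_names())

  no_plants <- full[!full$predictor %in% c("plant_similarity", "plant_richness"), ]
  expect_message(res6 <- run_table1(no_plants), "plant")
  expect_equal(nrow(res6), 6)
})
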