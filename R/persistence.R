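#' Usage metrics at designated sites in another season
#'
#' Looks up, for every hotspot and control cell of a designation, the four
#' space-use metrics (observations, individuals, species, revisits = distinct
#' days) in a usage table from some other season, zeros when the cell went
#' unused. The comparison is made on the very same 50 m cells that were
#' designated; no buffering.
#'
#' @param pairs `pairs` data frame of a [designate_sites()] result.
#' @param usage a [usage_table()] for the comparison season.
#' @return data frame: `plot_id, kind, row, col, n_obs, n_individuals,
#'   n_species, n_revisits`, with the usage period as attribute.
#' @export
usage_at_sites <- function(pairs, usage) {
  sites <- pairs_to_sites(pairs)
  u <- usage_at_cell(usage, sites$row, sites$col)
  out <- data.frame(plot_id = sites$plot_id, kind = sites$kind,
                    row = sites$row, col = sites$col,
                    n_obs = u$n_obs, n_individuals = u$n_individuals,
                    n_species = u$n_species, n_revisits = u$n_days)
  attr(out, "period") <- attr(usage, "period")
  out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' `W` is the sum of the (mid)ranks of the first group `x` in the pooled
#' sample. The p-value is exact (null distribution of the Mann-Whitney
#' statistic) when both groups are small (`min(n, m) <= exact_threshold`) and
#' there are no ties; otherwise the normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param x,y numeric vectors (e.g. hotspot and control metric values).
#' @param exact_threshold largest `min(n, m)` for which the exact null is
#'   used (default 10).
#' @return one-row data frame `statistic_w, p_value, n_x, n_y, method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_threshold = 10) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w <- sum(r[seq_len(n)])
  u <- w - n * (n + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && min(n, m) <= exact_threshold) {
    p <- if (u > n * m / 2) {
      2 * stats::pwilcox(u - 1, n, m, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, n, m)
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    nt <- n + m
    tie_sizes <- table(pooled)
    mu <- n * m / 2
    sigma2 <- (n * m / 12) *
      ((nt + 1) - sum(tie_sizes^3 - tie_sizes) / (nt * (nt - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all observations identical
    } else {
      cc <- sign(u - mu) * 0.5
      z <- (u - mu - cc) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  data.frame(statistic_w = w, p_value = p, n_x = n, n_y = m, method = method)
}

#' Hotspot persistence analysis
#'
#' Tests whether hotspots designated in year Y still attract more raptor
#' activity than their controls one and two years later: for each available
#' lag and each of the four space-use metrics, a two-sided Wilcoxon rank-sum
#' test of hotspot vs control values on the designated cells.
#'
#' @param pairs `pairs` data frame of the year-Y designation.
#' @param usage_by_year named list of [usage_table()]s, names = calendar
#'   years (e.g. `list("2020" = u2020, "2021" = u2021)`), each built from
#'   15-min resampled tracks of that year.
#' @param designation_year integer year the pairs were designated in.
#' @param lags lags (years after designation) to test; default `c(1, 2)`.
#'   A lag whose usage table is missing is skipped with a notice.
#' @return data frame: `designation_year, comparison_year, variable, W, p,
#'   n_hotspot, n_control`.
#' @export
persistence_analysis <- function(pairs, usage_by_year, designation_year,
                                 lags = c(1, 2)) {
  metrics <- c("n_obs", "n_individuals", "n_species", "n_revisits")
  rows <- list()
  for (lag in lags) {
    yr <- as.character(designation_year + lag)
    if (!yr %in% names(usage_by_year)) {
      message("no usage table for year ", yr, "; lag ", lag, " skipped")
      next
    }
    su <- usage_at_sites(pairs, usage_by_year[[yr]])
    hs <- su[su$kind == "hotspot", , drop = FALSE]
    ct <- su[su$kind == "control", , drop = FALSE]
    for (v in metrics) {
      wt <- wilcoxon_rank_sum(hs[[v]], ct[[v]])
      rows[[length(rows) + 1]] <- data.frame(
        designation_year = designation_year,
        comparison_year = as.integer(yr), variable = v,
        W = wt$statistic_w, p = wt$p_value,
        n_hotspot = wt$n_x, n_control = wt$n_y)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(designation_year = integer(), comparison_year = integer(),
                      variable = character(), W = numeric(), p = numeric(),
                      n_hotspot = integer(), n_control = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
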