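#' Theil--Sen trend estimate with Mann--Kendall significance
#'
#' Slope is the median of all pairwise slopes `(y_j - y_i)/(x_j - x_i)`,
#' i < j (pairs with equal x are skipped); the intercept is the median of
#' `y - slope * x`. Significance comes from the Mann--Kendall trend test,
#' the standard nonparametric companion, computed as the Kendall rank
#' correlation test of y against x ([stats::cor.test]); a bootstrap
#' confidence interval on the slope is available as an alternative.
#'
#' @param x numeric predictor (season labels / years).
#' @param y numeric response.
#' @param ci `"none"` (default) or `"bootstrap"` for a percentile bootstrap
#'   CI on the slope.
#' @param boot_n,boot_seed bootstrap replicates and seed.
#' @return A list of class `trend_result`: `slope`, `intercept`, `p`
#'   (Mann--Kendall two-sided), `n`, `method`, and optionally `ci`.
#' @export
theil_sen <- function(x, y, ci = c("none", "bootstrap"), boot_n = 999,
                      boot_seed = 1L) {
  ci <- match.arg(ci)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 finite observations", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("all x values identical: slope undefined", call. = FALSE)
  ts_slope <- function(x, y) {
    p <- utils::combn(length(x), 2)
    dx <- x[p[2, ]] - x[p[1, ]]
    sl <- (y[p[2, ]] - y[p[1, ]]) / dx
    stats::median(sl[dx != 0])
  }
  slope <- ts_slope(x, y)
  intercept <- stats::median(y - slope * x)
  p <- if (stats::sd(y) == 0) 1 else
    suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                     alternative = "two.sided"))$p.value
  res <- list(slope = slope, intercept = intercept, p = unname(p), n = n,
              method = "theil-sen + mann-kendall")
  if (ci == "bootstrap") {
    set.seed(boot_seed)
    bs <- replicate(boot_n, {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(x[idx])) < 2) NA_real_ else ts_slope(x[idx], y[idx])
    })
    res$ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE,
                              names = FALSE)
  }
  structure(res, class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Trend (%s): slope = %.6g per unit x, p = %.4g (n = %d)\n",
              x$method, x$slope, x$p, x$n))
  if (!is.null(x$ci))
    cat(sprintf("  bootstrap 95%% CI: [%.6g, %.6g]\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Paired t-test between two periods of per-cell means
#'
#' Pairs are grid cells: each cell contributes its mean of a summary
#' variable over the seasons of each period; the two-sided paired t-test is
#' run on the per-cell differences (B - A). Cells lacking data in either
#' period are dropped.
#'
#' @param summaries output of [annual_summaries] (one event type).
#' @param period_a,period_b length-2 periods (calendar years).
#' @param variable summary column to compare (default `"total"`, i.e.
#'   cumulative exceedance in degrees C or total rain-on-snow in mm).
#' @return A list of class `period_comparison`: `mean_diff` (B - A, variable
#'   units), `t`, `df`, `p`, `n_cells`, and the per-cell means.
#' @export
paired_period_test <- function(summaries, period_a, period_b,
                               variable = "total") {
  sa <- period_seasons(period_a); sb <- period_seasons(period_b)
  cellmean <- function(seasons) {
    s <- summaries[summaries$season %in% seasons, , drop = FALSE]
    agg <- stats::aggregate(s[[variable]],
                            by = list(lat = s$lat, lon = s$lon),
                            FUN = mean)
    names(agg)[3] <- "mean"
    agg
  }
  a <- cellmean(sa); b <- cellmean(sb)
  m <- merge(a, b, by = c("lat", "lon"), suffixes = c("_a", "_b"))
  m <- m[is.finite(m$mean_a) & is.finite(m$mean_b), , drop = FALSE]
  if (nrow(m) < 2)
    stop("need at least 2 cells with data in both periods", call. = FALSE)
  d <- m$mean_b - m$mean_a
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    # degenerate to numerical precision: all per-cell differences equal
    tt <- list(statistic = if (abs(mean(d)) <= 1e-10) 0 else
                 sign(mean(d)) * Inf,
               parameter = length(d) - 1,
               p.value = if (abs(mean(d)) <= 1e-10) 1 else 0)
  } else {
    tt <- stats::t.test(d)
  }
  structure(list(mean_diff = mean(d), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 n_cells = nrow(m), cells = m, variable = variable),
            class = "period_comparison")
}

#' @export
print.period_comparison <- function(x, ...) {
  cat(sprintf(
    "Paired period comparison (%s): mean diff (B - A) = %.4g, t(%g) = %.3f, p = %.4g, %d cells\n",
    x$variable, x$mean_diff, x$df, x$t, x$p, x$n_cells))
  invisible(x)
}

#' Mantel test of correlation between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with a one-sided
#' permutation p-value over simultaneous row/column permutations of the
#' second matrix. The p-value uses the add-one convention
#' `p = (1 + #{r_perm >= r_obs}) / (B + 1)`, so `p >= 1/(B+1)`. For small
#' matrices all permutations can be enumerated, in which case p is the
#' exact tail proportion over the full permutation distribution.
#'
#' @param d1,d2 symmetric distance matrices with zero diagonals, same order.
#' @param permutations number of random permutations (ignored when
#'   `exhaustive = TRUE`).
#' @param exhaustive enumerate all `n!` permutations (n <= 8 enforced).
#' @param seed seed for the random permutations.
#' @return A list of class `mantel_result`: `r`, `p`, `permutations`.
#' @export
mantel_test <- function(d1, d2, permutations = 999, exhaustive = FALSE,
                        seed = 1L) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  n <- nrow(d1)
  if (!isTRUE(all.equal(d1, t(d1))) || !isTRUE(all.equal(d2, t(d2))))
    stop("matrices must be symmetric", call. = FALSE)
  if (any(abs(diag(d1)) > 1e-12) || any(abs(diag(d2)) > 1e-12))
    stop("matrices must have zero diagonals", call. = FALSE)
  if (nrow(d2) != n) stop("matrices must have the same order", call. = FALSE)
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  if (stats::sd(v1) == 0 || stats::sd(d2[ut]) == 0)
    stop("constant distance matrix: correlation undefined", call. = FALSE)
  r_obs <- stats::cor(v1, d2[ut])
  perm_r <- function(p) stats::cor(v1, d2[p, p][ut])
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to n <= 8",
                    call. = FALSE)
    perms <- all_permutations(n)
    rs <- vapply(perms, perm_r, 0)
    p <- mean(rs >= r_obs - 1e-12)          # identity included in the set
    B <- length(perms)
  } else {
    set.seed(seed)
    rs <- replicate(permutations, perm_r(sample.int(n)))
    p <- (1 + sum(rs >= r_obs - 1e-12)) / (permutations + 1)
    B <- permutations
  }
  structure(list(r = r_obs, p = p, permutations = B,
                 exhaustive = exhaustive), class = "mantel_result")
}

# All permutations of 1..n as a list: insert n at every position of each
# permutation of 1..(n-1). n small by construction.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (pos in 0:(n - 1L)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = pos)
  }
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s%d permutations)\n",
              x$r, x$p, if (x$exhaustive) "exhaustive, " else "",
              x$permutations))
  invisible(x)
}

#' Winter precipitation trends for a region
#'
#' Builds per-season regional totals of winter rainfall and snowfall (mean
#' over the region's cells of each cell's seasonal total, mm) and their
#' ratio, then fits a trend per series. Ordinary least squares is the
#' default (matching how precipitation trends are usually reported as
#' linear trends); Theil--Sen is available. Seasons whose snowfall total is
#' zero are dropped from the ratio series, with the dropped count reported.
#'
#' @param cube a [climate_cube] with `pr` and `prsn`.
#' @param region optional box (see [arctic_regions]) to subset first.
#' @param method `"ols"` or `"theil-sen"`.
#' @return A list with `rain`, `snow`, `ratio` trend results (each with
#'   `slope` and `p`), the per-season series, and `ratio_dropped`.
#' @export
precip_trends <- function(cube, region = NULL,
                          method = c("ols", "theil-sen")) {
  method <- match.arg(method)
  if (is.null(cube$pr) || is.null(cube$prsn))
    stop("precip_trends needs 'pr' and 'prsn'", call. = FALSE)
  if (!is.null(region)) cube <- subset_cube(cube, region)
  lab <- winter_seasons(cube$dates)
  st <- season_table(cube)
  seasons <- st$season[st$complete]
  if (length(seasons) < 3) stop("region has fewer than 3 complete winters",
                                call. = FALSE)
  tot <- function(arr, s) {
    idx <- which(!is.na(lab) & lab == s)
    mean(apply(arr[, , idx, drop = FALSE], c(1, 2), sum), na.rm = TRUE)
  }
  rain <- vapply(seasons, function(s) tot(cube$pr, s), 0)
  snow <- vapply(seasons, function(s) tot(cube$prsn, s), 0)
  ok <- snow > 0
  ratio <- rain[ok] / snow[ok]
  fit1 <- function(x, y) {
    if (method == "ols") {
      f <- stats::lm(y ~ x)
      # perfect fits are legitimate for constructed series; the p-value is
      # then meaningless and reported as NA
      sf <- suppressWarnings(summary(f))
      pv <- sf$coefficients[2, 4]
      if (sf$sigma < 1e-10) pv <- NA_real_
      list(slope = unname(stats::coef(f)[2]), p = pv, n = length(x),
           method = "ols")
    } else {
      unclass(theil_sen(x, y))[c("slope", "p", "n", "method")]
    }
  }
  list(rain = fit1(seasons, rain),
       snow = fit1(seasons, snow),
       ratio = fit1(seasons[ok], ratio),
       series = data.frame(season = seasons, rain = rain, snow = snow),
       ratio_dropped = sum(!ok))
}
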