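test_that("Theil-Sen recovers exact lines and flat series", {
  x <- 1:10
  r <- theil_sen(x, 2 * x + 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)
  expect_lt(r$p, 0.01)
  flat <- theil_sen(x, rep(3, 10))
  expect_equal(flat$slope, 0)
  expect_equal(flat$p, 1)
  expect_error(theil_sen(rep(1, 5), rnorm(5)), "identical")
  expect_error(theil_sen(1:2, 1:2), "at least 3")
})

test_that("Theil-Sen slope equals the exhaustive pairwise-median oracle", {
  set.seed(8)
  for (rep in 1:5) {
    x <- 2000:2011
    y <- rnorm(12)
    slopes <- c()
    for (i in 1:11) for (j in (i + 1):12)
      slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
    expect_length(slopes, 66)
    expect_equal(theil_sen(x, y)$slope, median(slopes))
  }
})

test_that("Theil-Sen is shift-invariant and scale-equivariant in y", {
  set.seed(12)
  x <- 1:15; y <- 0.3 * x + rnorm(15)
  base <- theil_sen(x, y)
  expect_equal(theil_sen(x, y + 7)$slope, base$slope)
  expect_equal(theil_sen(x, 3 * y)$slope, 3 * base$slope)
  expect_equal(theil_sen(x, y + 7)$p, base$p)
})

test_that("paired period test equals its closed form and is antisymmetric", {
  cube <- small_sim_cube(seed = 41, years = c(1950, 1962))
  thr <- compute_threshold(cube, c(1950, 1956), prob = 0.9)
  sm <- annual_summaries(detect_warming_events(cube, thr), cube)
  pa <- c(1950, 1956); pb <- c(1956, 1962)
  pc <- paired_period_test(sm, pa, pb)
  # closed form t = mean(d) / (sd(d)/sqrt(n)) on the per-cell differences
  d <- pc$cells$mean_b - pc$cells$mean_a
  expect_equal(pc$t, mean(d) / (sd(d) / sqrt(length(d))))
  expect_equal(pc$mean_diff, mean(d))
  # antisymmetry
  rev <- paired_period_test(sm, pb, pa)
  expect_equal(rev$mean_diff, -pc$mean_diff)
  expect_equal(rev$t, -pc$t)
  expect_equal(rev$p, pc$p)
})

test_that("identical periods give zero difference and p = 1", {
  sm <- data.frame(lat = rep(1:3, 4), lon = 1,
                   season = rep(c(1951, 1952, 1961, 1962), each = 3),
                   total = rep(c(4, 5, 6), 4))
  pc <- paired_period_test(sm, c(1950, 1952), c(1960, 1962))
  expect_equal(pc$mean_diff, 0)
  expect_equal(pc$t, 0)
  expect_equal(pc$p, 1)
  # constant shift: difference recovered exactly
  sm$total[sm$season > 1960] <- sm$total[sm$season > 1960] + 2.8
  pc2 <- paired_period_test(sm, c(1950, 1952), c(1960, 1962))
  expect_equal(pc2$mean_diff, 2.8)
  expect_equal(pc2$p, 0)
})

test_that("Mantel r is Pearson on the upper triangle; self-test gives r = 1", {
  set.seed(3)
  n <- 6
  d <- as.matrix(dist(rnorm(n)))
  m <- mantel_test(d, d, permutations = 99)
  expect_equal(m$r, 1)
  d2 <- as.matrix(dist(rnorm(n)))
  m2 <- mantel_test(d, d2, permutations = 99)
  expect_equal(m2$r, cor(d[upper.tri(d)], d2[upper.tri(d2)]))
  expect_gte(m2$p, 1 / 100)
  expect_error(mantel_test(d, matrix(0, n, n)), "constant")
})

test_that("exhaustive Mantel p equals full-enumeration tail proportion", {
  set.seed(5)
  d1 <- as.matrix(dist(rnorm(5)))
  d2 <- as.matrix(dist(rnorm(5)))
  m <- mantel_test(d1, d2, exhaustive = TRUE)
  expect_equal(m$permutations, 120L)
  # independent oracle: enumerate permutations via expand.grid filtering
  tup <- as.matrix(expand.grid(1:5, 1:5, 1:5, 1:5, 1:5))
  perms <- tup[apply(tup, 1, function(r) length(unique(r)) == 5), ,
               drop = FALSE]
  expect_equal(nrow(perms), 120)
  ut <- upper.tri(d1)
  r_obs <- cor(d1[ut], d2[ut])
  rs <- apply(perms, 1, function(p) cor(d1[ut], d2[p, p][ut]))
  expect_equal(m$p, mean(rs >= r_obs - 1e-12))
})

test_that("Mantel agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(14)
  d1 <- as.matrix(dist(rnorm(12)))
  d2 <- as.matrix(dist(rnorm(12)))
  ours <- mantel_test(d1, d2, permutations = 999, seed = 2)
  ref <- vegan::mantel(d1, d2, permutations = 999)
  expect_equal(ours$r, unname(ref$statistic))
  expect_lt(abs(ours$p - ref$signif), 0.06)
})

test_that("Mantel p is roughly uniform under independence", {
  set.seed(77)
  ps <- replicate(60, {
    d1 <- as.matrix(dist(rnorm(7)))
    d2 <- as.matrix(dist(rnorm(7)))
    mantel_test(d1, d2, permutations = 99,
                seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps), 0.33)
  expect_lt(mean(ps), 0.67)
  expect_gt(mean(ps <= 0.25), 0.1)
})

test_that("precipitation trends recover constructed slopes", {
  # build a cube with prescribed per-season rainfall/snowfall totals
  cfg <- climate_sim_config(lat_range = c(66, 67), lon_range = c(20, 21),
                            years = c(1950, 1965), rain_prob = 0,
                            noise_sd = 0, trend = 0, seed = 1)
  cube <- simulate_climate(cfg)
  lab <- winter_seasons(cube$dates)
  seasons <- sort(unique(lab[!is.na(lab)]))
  for (s in seasons) {
    idx <- which(!is.na(lab) & lab == s)
    # rainfall grows 0.2 per season; snowfall constant
    cube$pr[, , idx[1]] <- 0.2 * (s - seasons[1])
    cube$prsn[, , idx[2]] <- 5
  }
  tr <- precip_trends(cube, method = "ols")
  expect_equal(tr$rain$slope, 0.2, tolerance = 1e-8)
  expect_equal(tr$snow$slope, 0, tolerance = 1e-8)
  # rain = snow each season -> ratio constant at 1, slope 0
  cube$pr <- cube$prsn
  tr2 <- precip_trends(cube, method = "theil-sen")
  expect_equal(tr2$ratio$slope, 0)
  expect_equal(tr2$ratio_dropped, 0)
})
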