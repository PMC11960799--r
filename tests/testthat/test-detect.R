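test_that("baseline threshold matches a sort-based percentile oracle", {
  # constant series -> threshold equals the constant
  cube <- one_cell_cube("1950-01-01", "1980-12-31", tmax = 5)
  thr <- compute_threshold(cube)
  expect_equal(thr$threshold[1, 1], 5)

  # known series: type-7 interpolation computed by hand from sorted values
  cube2 <- small_sim_cube(seed = 2, nlat = 2, nlon = 2,
                          years = c(1950, 1980))
  thr2 <- compute_threshold(cube2, c(1950, 1980), prob = 0.99)
  lab <- winter_seasons(cube2$dates)
  use <- !is.na(lab) & lab %in% 1951:1980
  for (i in 1:2) for (j in 1:2) {
    v <- sort(cube2$tasmax[i, j, use])
    h <- (length(v) - 1) * 0.99 + 1
    expected <- v[floor(h)] + (h - floor(h)) * (v[floor(h) + 1] - v[floor(h)])
    expect_equal(thr2$threshold[i, j], expected)
  }
})

test_that("the worked warming-intensity example scores 10", {
  cube <- one_cell_cube("1999-12-01", "2000-01-31", tmax = -10)
  cube$tasmax[1, 1, 10:11] <- c(5, 7)
  ev <- detect_warming_events(cube, matrix(3, 1, 1))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$length, 2L)
  expect_equal(ev$intensity, (5 - 3) * 1 + (7 - 3) * 2)  # 10
  expect_equal(ev$total, 6)
  expect_equal(ev$series[[1]], c(2, 4))
  # single-day event: intensity equals its exceedance
  cube$tasmax[1, 1, 11] <- -10
  ev1 <- detect_warming_events(cube, matrix(3, 1, 1))
  expect_equal(ev1$intensity, ev1$total)
})

test_that("warming detection matches the brute-force oracle on random cubes", {
  for (seed in 1:5) {
    cube <- small_sim_cube(seed = seed)
    thr <- compute_threshold(cube, c(1950, 1955), prob = 0.95)
    ev <- detect_warming_events(cube, thr)
    expect_true(all(ev$intensity >= 0))
    orc <- oracle_warming(cube, thr$threshold)
    got <- event_runs(ev, cube)
    for (key in names(orc))
      expect_identical(got[[key]], orc[[key]]$runs, label = key)
  }
})

test_that("raising the threshold never increases detected warming days", {
  cube <- small_sim_cube(seed = 11)
  lo <- compute_threshold(cube, c(1950, 1955), prob = 0.9)
  hi <- compute_threshold(cube, c(1950, 1955), prob = 0.99)
  n_days <- function(ev) sum(ev$length)
  expect_gte(n_days(detect_warming_events(cube, lo)),
             n_days(detect_warming_events(cube, hi)))
})

test_that("detection depends only on winter days", {
  cube <- small_sim_cube(seed = 13)
  thr <- compute_threshold(cube, c(1950, 1955), prob = 0.95)
  ev <- detect_warming_events(cube, thr)
  # perturb all April-September values: identical events
  m <- as.integer(format(cube$dates, "%m"))
  summer <- m >= 4 & m <= 9
  cube2 <- cube
  cube2$tasmax[, , summer] <- cube2$tasmax[, , summer] + 50
  ev2 <- detect_warming_events(cube2, thr)
  expect_equal(ev[setdiff(names(ev), "series")],
               ev2[setdiff(names(ev2), "series")])
  # delete April-September days outright: identical events
  keep <- !summer
  cube3 <- climate_cube(cube$lat, cube$lon, cube$dates[keep],
                        tasmax = cube$tasmax[, , keep, drop = FALSE])
  ev3 <- detect_warming_events(cube3, thr)
  expect_equal(ev$start, ev3$start)
  expect_equal(ev$intensity, ev3$intensity)
})

test_that("missing data disqualify days and break runs", {
  cube <- one_cell_cube("1999-12-01", "2000-01-31", tmax = 6)
  cube$tasmax[1, 1, 5] <- NA
  ev <- detect_warming_events(cube, matrix(0, 1, 1))
  expect_equal(nrow(ev), 2)
  expect_equal(sum(ev$length), length(cube$dates) - 1)
})

test_that("events are truncated at the season boundary (Mar 31 -> Apr 1)", {
  cube <- one_cell_cube("2000-03-25", "2000-04-10", tmax = 6)
  ev <- detect_warming_events(cube, matrix(0, 1, 1))
  expect_equal(nrow(ev), 1)
  expect_equal(as.character(max(ev$start + ev$length - 1)), "2000-03-31")
})

test_that("detection is cell-local: permuting cells permutes events", {
  cube <- small_sim_cube(seed = 17, nlat = 2, nlon = 2)
  thr <- compute_threshold(cube, c(1950, 1955), prob = 0.95)
  ev <- detect_warming_events(cube, thr)
  # swap the two latitude rows of data and thresholds
  cube2 <- cube
  cube2$tasmax <- cube$tasmax[2:1, , , drop = FALSE]
  thr2 <- thr; thr2$threshold <- thr$threshold[2:1, , drop = FALSE]
  ev2 <- detect_warming_events(cube2, thr2)
  remap <- ev2
  remap$lat <- cube$lat[3 - match(ev2$lat, cube$lat)]
  ord <- function(d) d[order(d$lat, d$lon, d$start), c("lat", "lon",
                                                       "start", "length",
                                                       "intensity")]
  a <- ord(ev); b <- ord(remap)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("the worked rain-on-snow intensity example scores 19", {
  cube <- one_cell_cube("1999-12-01", "2000-01-31", tmax = -10,
                        rain = 0, snow = 10)
  cube$tasmax[1, 1, 10:11] <- 2
  cube$pr[1, 1, 10:11] <- c(5, 7)
  ev <- detect_ros_events(cube)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$intensity, 5 * 1 + 7 * 2)  # 19
  expect_equal(ev$total, 12)
})

test_that("the refreeze criterion vetoes candidate rain-on-snow events", {
  cube <- one_cell_cube("1999-12-01", "2000-01-31", tmax = -10,
                        rain = 0, snow = 10)
  cube$tasmax[1, 1, 10] <- 2
  cube$pr[1, 1, 10] <- 5
  cube$tasmax[1, 1, 11:13] <- 2          # stays warm: no refreeze
  expect_equal(nrow(detect_ros_events(cube)), 0)
  cube$tasmax[1, 1, 11:13] <- c(1, -1, -2)  # mean < 0: refreeze holds
  expect_equal(nrow(detect_ros_events(cube)), 1)
  # mean exactly 0 fails the strict < 0 criterion
  cube$tasmax[1, 1, 11:13] <- c(2, -1, -1)
  expect_equal(nrow(detect_ros_events(cube)), 0)
})

test_that("events too close to the record end are discarded and logged", {
  cube <- one_cell_cube("1999-12-01", "1999-12-20", tmax = -10,
                        rain = 0, snow = 10)
  nt <- length(cube$dates)
  cube$tasmax[1, 1, nt - 1] <- 2
  cube$pr[1, 1, nt - 1] <- 5
  ev <- detect_ros_events(cube)
  expect_equal(nrow(ev), 0)
  expect_equal(attr(ev, "discarded_no_lookahead"), 1L)
})

test_that("rain-on-snow detection matches the four-condition oracle", {
  for (seed in c(23, 29, 31)) {
    cube <- small_sim_cube(seed = seed)
    ev <- detect_ros_events(cube)
    orc <- oracle_ros(cube)
    got <- event_runs(ev, cube)
    for (key in names(orc))
      expect_identical(got[[key]], orc[[key]]$runs, label = key)
  }
})

test_that("summaries conserve exceedance and handle empty seasons", {
  cube <- small_sim_cube(seed = 37)
  thr <- compute_threshold(cube, c(1950, 1955), prob = 0.95)
  ev <- detect_warming_events(cube, thr)
  sm <- annual_summaries(ev, cube)
  # conservation: per cell-season total equals flat recomputation
  for (r in sample(nrow(sm), 25)) {
    sel <- ev$lat == sm$lat[r] & ev$lon == sm$lon[r] &
      ev$season == sm$season[r]
    expect_equal(sm$total[r], sum(ev$total[sel]))
    expect_equal(sm$n_events[r], sum(sel))
    if (any(sel)) {
      expect_equal(sm$mean_length[r], mean(ev$length[sel]))
      expect_equal(sm$mean_intensity[r], mean(ev$intensity[sel]))
    } else {
      expect_equal(sm$mean_length[r], 0)
    }
  }
  # exceedance series (2, 4) sums to 6
  expect_equal(sum(c(2, 4)), 6)
})

test_that("emergence flags recover a planted pattern", {
  cube <- small_sim_cube(seed = 1, nlat = 2, nlon = 2,
                         years = c(1950, 1970))
  # fabricate summaries directly: cell (1,1) events only late, (2,2) only
  # early, (1,2) both, (2,1) never
  sm <- annual_summaries(empty <- detect_warming_events(
    cube, matrix(1e6, 2, 2)), cube)
  set1 <- function(lat, lon, seasons) {
    idx <- sm$lat == lat & sm$lon == lon & sm$season %in% seasons
    sm$n_events[idx] <<- 1
  }
  set1(cube$lat[1], cube$lon[1], 1961:1970)
  set1(cube$lat[2], cube$lon[2], 1951:1960)
  set1(cube$lat[1], cube$lon[2], c(1951:1960, 1961:1970))
  fl <- emergence_flags(sm, c(1950, 1960), c(1960, 1970))
  get <- function(lat, lon) fl$flag[fl$lat == lat & fl$lon == lon]
  expect_equal(get(cube$lat[1], cube$lon[1]), "new")
  expect_equal(get(cube$lat[2], cube$lon[2]), "vanished")
  expect_equal(get(cube$lat[1], cube$lon[2]), "both-periods")
  expect_equal(get(cube$lat[2], cube$lon[1]), "neither")
  pr <- attr(fl, "proportions")
  expect_equal(unname(pr["new"]), 1 / 3)
  expect_error(emergence_flags(sm, c(1950, 1960), c(1955, 1970)),
               "overlap")
})
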