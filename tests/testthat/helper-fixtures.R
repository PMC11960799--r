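# Builders for tiny in-code fixtures used across the suite.

# One-cell cube over a date range with given daily series (recycled).
one_cell_cube <- function(from, to, tmax, rain = NULL, snow = NULL,
                          lat = 66.5, lon = 20.5) {
  dates <- seq(as.Date(from), as.Date(to), by = "day")
  nt <- length(dates)
  arr <- function(v) if (is.null(v)) NULL else
    array(rep_len(v, nt), c(1, 1, nt))
  climate_cube(lat, lon, dates, tasmax = arr(tmax), pr = arr(rain),
               swe = arr(snow))
}

# Random multi-cell cube via the seeded generator, small defaults.
small_sim_cube <- function(seed, nlat = 3, nlon = 3,
                           years = c(1950, 1955)) {
  cfg <- climate_sim_config(lat_range = c(66, 66 + nlat),
                            lon_range = c(20, 20 + nlon),
                            years = years, seed = seed)
  simulate_climate(cfg)
}

# Independent per-day brute-force warming detection oracle: returns the
# set of qualifying day indices and a segmentation into consecutive runs,
# per cell, using nothing but direct condition checks and an index walk.
oracle_warming <- function(cube, thr_mat, strict = TRUE) {
  months <- as.integer(format(cube$dates, "%m"))
  out <- list()
  for (i in seq_along(cube$lat)) for (j in seq_along(cube$lon)) {
    days <- integer()
    for (t in seq_along(cube$dates)) {
      tm <- cube$tasmax[i, j, t]
      if (is.na(tm) || is.na(thr_mat[i, j])) next
      if (!(months[t] >= 10 || months[t] <= 3)) next
      hit <- if (strict) tm > thr_mat[i, j] else tm >= thr_mat[i, j]
      if (hit) days <- c(days, t)
    }
    runs <- list()
    if (length(days)) {
      start <- days[1]; prev <- days[1]
      for (d in days[-1]) {
        if (d == prev + 1) prev <- d
        else { runs[[length(runs) + 1]] <- c(start, prev); start <- prev <- d }
      }
      runs[[length(runs) + 1]] <- c(start, prev)
    }
    out[[paste(i, j)]] <- list(days = days, runs = runs)
  }
  out
}

# Independent brute-force rain-on-snow oracle (four conditions + refreeze).
oracle_ros <- function(cube, rain_min = 3, snow_min = 3, tmax_min = 1,
                       refreeze_max = 0, lookahead = 3) {
  months <- as.integer(format(cube$dates, "%m"))
  nt <- length(cube$dates)
  out <- list()
  for (i in seq_along(cube$lat)) for (j in seq_along(cube$lon)) {
    days <- integer()
    for (t in seq_len(nt)) {
      tm <- cube$tasmax[i, j, t]; rn <- cube$pr[i, j, t]
      sw <- cube$swe[i, j, t]
      if (is.na(tm) || is.na(rn) || is.na(sw)) next
      if (!(months[t] >= 10 || months[t] <= 3)) next
      if (rn >= rain_min && sw >= snow_min && tm > tmax_min)
        days <- c(days, t)
    }
    runs <- list()
    if (length(days)) {
      start <- days[1]; prev <- days[1]
      flush <- function(runs, start, prev) {
        ahead <- prev + seq_len(lookahead)
        if (max(ahead) <= nt && !anyNA(cube$tasmax[i, j, ahead]) &&
            mean(cube$tasmax[i, j, ahead]) < refreeze_max)
          runs[[length(runs) + 1]] <- c(start, prev)
        runs
      }
      for (d in days[-1]) {
        if (d == prev + 1) prev <- d
        else { runs <- flush(runs, start, prev); start <- prev <- d }
      }
      runs <- flush(runs, start, prev)
    }
    out[[paste(i, j)]] <- list(days = days, runs = runs)
  }
  out
}

# Event data frame -> per-cell list of (start index, end index) runs,
# comparable to the oracles above.
event_runs <- function(events, cube) {
  out <- list()
  for (i in seq_along(cube$lat)) for (j in seq_along(cube$lon)) {
    sel <- events$lat == cube$lat[i] & events$lon == cube$lon[j]
    ev <- events[sel, , drop = FALSE]
    ev <- ev[order(ev$start), , drop = FALSE]
    runs <- lapply(seq_len(nrow(ev)), function(r) {
      s <- match(ev$start[r], cube$dates)
      c(s, s + ev$length[r] - 1L)
    })
    out[[paste(i, j)]] <- runs
  }
  out
}

# Simulated effect-size table with SMDH columns attached.
sim_meta_data <- function(cfg) {
  sim <- simulate_effect_sizes(cfg)
  es <- smdh(sim$records$n_c, sim$records$mean_c, sim$records$sd_c,
             sim$records$n_r, sim$records$mean_r, sim$records$sd_r)
  sim$records$yi <- es$yi
  sim$records$vi <- es$vi
  sim
}
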