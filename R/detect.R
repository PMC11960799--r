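#' Baseline percentile thresholds for extreme winter warming
#'
#' Per grid cell, the 99th percentile (by default) of daily maximum winter
#' temperature over a baseline climatological period (default 1950--1980).
#' The percentile convention is linear interpolation between order statistics
#' (R quantile type 7); it is recorded in the result because percentile
#' conventions differ between tools.
#'
#' @param cube a [climate_cube] with `tasmax`.
#' @param baseline length-2 integer period, e.g. `c(1950, 1980)`; winters
#'   wholly inside the period are used (see [period_seasons]).
#' @param prob percentile as a probability, default 0.99.
#' @return A list of class `baseline_threshold` with a `nlat x nlon` matrix
#'   `threshold` (degrees C; `NA` where a cell has no baseline data),
#'   plus `baseline`, `prob` and `quantile_type`.
#' @export
compute_threshold <- function(cube, baseline = c(1950, 1980), prob = 0.99) {
  lab <- winter_seasons(cube$dates)
  use <- !is.na(lab) & lab %in% period_seasons(baseline)
  if (!any(use)) stop("no baseline winters present in the cube",
                      call. = FALSE)
  sub <- cube$tasmax[, , use, drop = FALSE]
  thr <- apply(sub, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else stats::quantile(v, prob, type = 7,
                                                  names = FALSE)
  })
  structure(list(threshold = thr, baseline = baseline, prob = prob,
                 quantile_type = 7L, lat = cube$lat, lon = cube$lon),
            class = "baseline_threshold")
}

# Segment a per-day logical qualifying mask into maximal runs of consecutive
# TRUE days. NA counts as FALSE (and so breaks runs). Returns a data frame
# with 1-based start index and length per run.
segment_runs <- function(qual) {
  qual[is.na(qual)] <- FALSE
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep])
}

# Day-weighted intensity: sum of series[d] * d with d the 1-based day index
# within the event.
event_intensity <- function(series) sum(series * seq_along(series))

empty_events <- function() {
  data.frame(type = character(), lat = numeric(), lon = numeric(),
             season = integer(), start = as.Date(character()),
             length = integer(), max_temp = numeric(), total = numeric(),
             intensity = numeric(), series = I(list()))
}

#' Detect extreme winter warming events
#'
#' A day qualifies iff it is a winter (October--March) day and its daily
#' maximum temperature strictly exceeds the cell's baseline threshold.
#' Maximal runs of consecutive qualifying days within one cell form one
#' event; a run is truncated at March 31 so no event spans a season
#' boundary. Missing data on a day disqualifies it and breaks runs. The
#' per-day exceedance is `tasmax - threshold`; the event intensity is the
#' day-weighted sum `sum(exceedance_d * d)` with `d` the 1-based day index
#' within the event (so the worked two-day example with maxima 5 and 7
#' degrees C over a 3 degree threshold scores (5-3)*1 + (7-3)*2 = 10).
#'
#' @param cube a [climate_cube] with `tasmax`.
#' @param thresholds a [compute_threshold] result (or a numeric matrix of
#'   per-cell thresholds).
#' @param strict use strict `>` for the exceedance test (default, matching
#'   "exceeded"); `FALSE` switches to `>=`.
#' @return A data frame of events with columns `type` ("warming"), `lat`,
#'   `lon`, `season`, `start`, `length`, `max_temp`, `total` (sum of the
#'   exceedance series, degrees C), `intensity`, and a list column `series`
#'   holding each event's per-day exceedance series.
#' @export
detect_warming_events <- function(cube, thresholds, strict = TRUE) {
  thr <- if (inherits(thresholds, "baseline_threshold"))
    thresholds$threshold else thresholds
  if (!all(dim(thr) == c(length(cube$lat), length(cube$lon))))
    stop("threshold grid does not cover the cube's cells", call. = FALSE)
  lab <- winter_seasons(cube$dates)
  out <- vector("list", length(cube$lat) * length(cube$lon))
  k <- 0L
  for (i in seq_along(cube$lat)) for (j in seq_along(cube$lon)) {
    k <- k + 1L
    if (is.na(thr[i, j])) next                    # no baseline: no detection
    tmax <- cube$tasmax[i, j, ]
    qual <- !is.na(lab) &
      (if (strict) tmax > thr[i, j] else tmax >= thr[i, j])
    qual[is.na(qual)] <- FALSE
    runs <- segment_runs(qual & !is.na(tmax))
    if (!nrow(runs)) next
    # split runs at season boundaries (a run crossing Mar 31 -> Oct 1 is
    # impossible, but guard against label changes within a run anyway)
    ev <- do.call(rbind, lapply(seq_len(nrow(runs)), function(r) {
      idx <- runs$start[r] + seq_len(runs$length[r]) - 1L
      pieces <- split(idx, lab[idx])
      do.call(rbind, lapply(pieces, function(pi) {
        ser <- tmax[pi] - thr[i, j]
        data.frame(type = "warming", lat = cube$lat[i], lon = cube$lon[j],
                   season = lab[pi[1]], start = cube$dates[pi[1]],
                   length = length(pi), max_temp = max(tmax[pi]),
                   total = sum(ser), intensity = event_intensity(ser),
                   series = I(list(ser)))
      }))
    }))
    out[[k]] <- ev
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(empty_events())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect rain-on-snow events
#'
#' A day qualifies iff it is a winter day with rainfall >= `rain_min` mm,
#' snow depth >= `snow_min` mm SWE, and daily maximum temperature strictly
#' above `tmax_min` degrees C. Consecutive qualifying days form a candidate
#' event, retained iff the mean of the daily maxima over the `lookahead`
#' days following the event's last day is below `refreeze_max` degrees C
#' (the refreeze criterion; the lookahead may use April days for events
#' ending in late March). Candidates with fewer than `lookahead` days of
#' record after them are discarded and counted in the diagnostics attribute
#' `attr(result, "discarded_no_lookahead")`. Event intensity is the
#' day-weighted rainfall sum `sum(rain_d * d)` (so a two-day event with 5 mm
#' then 7 mm scores 5*1 + 7*2 = 19).
#'
#' @param cube a [climate_cube] with `tasmax`, `pr` and `swe`.
#' @param rain_min,snow_min rain (mm) and snow-depth (mm SWE) thresholds,
#'   both inclusive by default; set `strict_rain`/`strict_snow` to use `>`.
#' @param tmax_min temperature criterion (degrees C, strict `>`).
#' @param refreeze_max upper bound (exclusive) on the mean post-event
#'   maximum temperature, degrees C.
#' @param lookahead number of days after the event used for the refreeze
#'   test.
#' @param strict_rain,strict_snow switch the rain/snow comparisons to
#'   strict `>`.
#' @return A data frame of events like [detect_warming_events], with
#'   `total` the event's total rainfall (mm) and `series` the per-day
#'   rainfall series.
#' @export
detect_ros_events <- function(cube, rain_min = 3, snow_min = 3,
                              tmax_min = 1, refreeze_max = 0, lookahead = 3,
                              strict_rain = FALSE, strict_snow = FALSE) {
  for (v in c("tasmax", "pr", "swe"))
    if (is.null(cube[[v]]))
      stop("rain-on-snow detection needs variable '", v, "'", call. = FALSE)
  lab <- winter_seasons(cube$dates)
  nt <- length(cube$dates)
  out <- list(); discarded <- 0L
  for (i in seq_along(cube$lat)) for (j in seq_along(cube$lon)) {
    tmax <- cube$tasmax[i, j, ]; rain <- cube$pr[i, j, ]
    snow <- cube$swe[i, j, ]
    ok_rain <- if (strict_rain) rain > rain_min else rain >= rain_min
    ok_snow <- if (strict_snow) snow > snow_min else snow >= snow_min
    qual <- !is.na(lab) & !is.na(tmax) & !is.na(rain) & !is.na(snow) &
      ok_rain & ok_snow & tmax > tmax_min
    qual[is.na(qual)] <- FALSE
    runs <- segment_runs(qual)
    if (!nrow(runs)) next
    for (r in seq_len(nrow(runs))) {
      idx <- runs$start[r] + seq_len(runs$length[r]) - 1L
      for (piece in split(idx, lab[idx])) {       # never span seasons
        last <- piece[length(piece)]
        ahead <- last + seq_len(lookahead)
        if (max(ahead) > nt) { discarded <- discarded + 1L; next }
        post <- tmax[ahead]
        if (anyNA(post)) { discarded <- discarded + 1L; next }
        if (mean(post) >= refreeze_max) next      # refreeze criterion fails
        ser <- rain[piece]
        out[[length(out) + 1L]] <- data.frame(
          type = "ros", lat = cube$lat[i], lon = cube$lon[j],
          season = lab[piece[1]], start = cube$dates[piece[1]],
          length = length(piece), max_temp = max(tmax[piece]),
          total = sum(ser), intensity = event_intensity(ser),
          series = I(list(ser)))
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_events()
  rownames(res) <- NULL
  attr(res, "discarded_no_lookahead") <- discarded
  res
}

#' Per cell-season summaries of detected events
#'
#' For every grid cell, winter season in the cube, and event type present in
#' `events`: the event count, cumulative exceedance / total rain-on-snow
#' (the sum of each member event's series, i.e. `total`), mean event length,
#' mean intensity, and maximum temperature reached. Cell-seasons with no
#' events get zeros (`max_temp` is `NA` there).
#'
#' @param events a data frame from [detect_warming_events] or
#'   [detect_ros_events] (or both, row-bound).
#' @param cube the [climate_cube] the events were detected on.
#' @param complete_only restrict to complete winter seasons (default TRUE).
#' @return A data frame with columns `lat`, `lon`, `season`, `type`,
#'   `n_events`, `total`, `mean_length`, `mean_intensity`, `max_temp`.
#' @export
annual_summaries <- function(events, cube, complete_only = TRUE) {
  st <- season_table(cube)
  if (complete_only) st <- st[st$complete, , drop = FALSE]
  types <- unique(events$type)
  if (!length(types)) types <- "warming"
  grid <- expand.grid(lat = cube$lat, lon = cube$lon, season = st$season,
                      type = types, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  key <- function(d) paste(d$lat, d$lon, d$season, d$type, sep = "|")
  grid$n_events <- 0; grid$total <- 0
  grid$mean_length <- 0; grid$mean_intensity <- 0; grid$max_temp <- NA_real_
  if (nrow(events)) {
    ev <- events[events$season %in% st$season, , drop = FALSE]
    if (nrow(ev)) {
      spl <- split(ev, key(ev))
      m <- match(names(spl), key(grid))
      grid$n_events[m] <- vapply(spl, nrow, 0L)
      grid$total[m] <- vapply(spl, function(d) sum(d$total), 0)
      grid$mean_length[m] <- vapply(spl, function(d) mean(d$length), 0)
      grid$mean_intensity[m] <- vapply(spl, function(d) mean(d$intensity), 0)
      grid$max_temp[m] <- vapply(spl, function(d) max(d$max_temp), 0)
    }
  }
  grid
}

#' Event emergence between two periods
#'
#' Flags each grid cell as `"new"` (events in period B but none in A),
#' `"vanished"` (the reverse), `"both-periods"`, or `"neither"`, and reports
#' the proportions of flagged cells among cells with any events.
#'
#' @param summaries output of [annual_summaries] for one event type.
#' @param period_a,period_b disjoint length-2 periods (calendar years).
#' @return A data frame (`lat`, `lon`, `flag`) with a `proportions`
#'   attribute (named proportions of "new" and "vanished" among cells with
#'   at least one event in either period).
#' @export
emergence_flags <- function(summaries, period_a, period_b) {
  sa <- period_seasons(period_a); sb <- period_seasons(period_b)
  if (length(intersect(sa, sb)))
    stop("periods overlap", call. = FALSE)
  cells <- unique(summaries[, c("lat", "lon")])
  cnt <- function(lat, lon, seasons) {
    s <- summaries[summaries$lat == lat & summaries$lon == lon &
                     summaries$season %in% seasons, "n_events"]
    sum(s)
  }
  flag <- character(nrow(cells))
  for (r in seq_len(nrow(cells))) {
    a <- cnt(cells$lat[r], cells$lon[r], sa) > 0
    b <- cnt(cells$lat[r], cells$lon[r], sb) > 0
    flag[r] <- if (a && b) "both-periods" else if (b) "new" else
      if (a) "vanished" else "neither"
  }
  res <- cbind(cells, flag = flag)
  active <- sum(flag != "neither")
  attr(res, "proportions") <- c(
    new = if (active) sum(flag == "new") / active else NA_real_,
    vanished = if (active) sum(flag == "vanished") / active else NA_real_)
  rownames(res) <- NULL
  res
}
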