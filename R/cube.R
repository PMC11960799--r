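#' Daily gridded climate cube
#'
#' Container for daily gridded climate fields on a regular latitude/longitude
#' grid: daily maximum temperature (`tasmax`, degrees C), daily total rainfall
#' (`pr`, mm/day), snow-water-equivalent snow depth (`swe`, mm) and,
#' optionally, daily snowfall (`prsn`, mm/day water equivalent). Each field is
#' a `nlat x nlon x ntime` array; coordinates are cell centres in degrees
#' north / degrees east.
#'
#' @param lat,lon numeric vectors of cell-centre coordinates, equally spaced.
#' @param dates a `Date` vector of consecutive days.
#' @param tasmax,pr,swe arrays of dimension `c(length(lat), length(lon),
#'   length(dates))`. `pr` and `swe` must be non-negative.
#' @param prsn optional snowfall array with the same dimensions.
#' @param meta optional list of provenance metadata.
#' @return An object of class `climate_cube`.
#' @export
climate_cube <- function(lat, lon, dates, tasmax, pr = NULL, swe = NULL,
                         prsn = NULL, meta = list()) {
  if (!inherits(dates, "Date")) dates <- as.Date(dates)
  dm <- c(length(lat), length(lon), length(dates))
  chk <- function(x, nm, nonneg = FALSE) {
    if (is.null(x)) return(NULL)
    if (!is.array(x) || !identical(dim(x), as.integer(dm)))
      stop(sprintf("field '%s' must be an array of dim %s", nm,
                   paste(dm, collapse = "x")), call. = FALSE)
    if (nonneg && any(x < 0, na.rm = TRUE))
      stop(sprintf("field '%s' contains negative values", nm), call. = FALSE)
    x
  }
  if (length(lat) > 2 && diff(range(diff(lat))) > 1e-8)
    stop("latitude grid is not uniformly spaced", call. = FALSE)
  if (length(lon) > 2 && diff(range(diff(lon))) > 1e-8)
    stop("longitude grid is not uniformly spaced", call. = FALSE)
  structure(list(
    lat = as.numeric(lat), lon = as.numeric(lon), dates = dates,
    tasmax = chk(tasmax, "tasmax"),
    pr = chk(pr, "pr", nonneg = TRUE),
    swe = chk(swe, "swe", nonneg = TRUE),
    prsn = chk(prsn, "prsn", nonneg = TRUE),
    res = if (length(lat) > 1) abs(diff(lat)[1]) else NA_real_,
    meta = meta
  ), class = "climate_cube")
}

#' @export
print.climate_cube <- function(x, ...) {
  vars <- intersect(c("tasmax", "pr", "swe", "prsn"), names(x))
  vars <- vars[!vapply(x[vars], is.null, TRUE)]
  cat("climate_cube:", length(x$lat), "x", length(x$lon), "cells,",
      length(x$dates), "days (", format(min(x$dates)), "to",
      format(max(x$dates)), ")\n")
  cat("  variables:", paste(vars, collapse = ", "), "\n")
  cat("  lat:", min(x$lat), "..", max(x$lat), " lon:", min(x$lon), "..",
      max(x$lon), " res:", x$res, "deg\n")
  invisible(x)
}

cube_vars <- function(cube) {
  v <- c("tasmax", "pr", "swe", "prsn")
  v[vapply(v, function(n) !is.null(cube[[n]]), TRUE)]
}

#' Winter-season labels for dates
#'
#' The Arctic winter season runs October through March. The winter spanning
#' October of year Y-1 to March of year Y is labelled Y, so each season's
#' days are contiguous in time. Days in April--September belong to no season
#' and get `NA`.
#'
#' @param dates a `Date` vector.
#' @return Integer vector of season labels (NA outside October--March).
#' @export
winter_seasons <- function(dates) {
  dates <- as.Date(dates)
  m <- as.integer(format(dates, "%m"))
  y <- as.integer(format(dates, "%Y"))
  out <- rep(NA_integer_, length(dates))
  out[m >= 10L] <- y[m >= 10L] + 1L
  out[m <= 3L] <- y[m <= 3L]
  out
}

#' Tabulate winter seasons present in a cube
#'
#' @param cube a [climate_cube].
#' @return A data frame with one row per season: label, number of member
#'   days, and whether the season is complete (contains both an October 1st
#'   and a March 31st).
#' @export
season_table <- function(cube) {
  lab <- winter_seasons(cube$dates)
  keep <- !is.na(lab)
  if (!any(keep))
    return(data.frame(season = integer(), n_days = integer(),
                      complete = logical()))
  md <- format(cube$dates[keep], "%m-%d")
  spl <- split(md, lab[keep])
  data.frame(
    season = as.integer(names(spl)),
    n_days = lengths(spl),
    complete = vapply(spl, function(d) ("10-01" %in% d) && ("03-31" %in% d),
                      TRUE),
    row.names = NULL
  )
}

#' Seasons wholly inside a calendar period
#'
#' A period `c(1950, 1980)` selects the winters lying entirely within
#' October 1950 -- March 1980, i.e. season labels 1951..1980.
#' @param period length-2 integer vector (start year, end year).
#' @return Integer vector of season labels.
#' @export
period_seasons <- function(period) {
  stopifnot(length(period) == 2, period[2] > period[1])
  seq.int(period[1] + 1L, period[2])
}

#' Spatially aggregate a cube to a coarser grid
#'
#' Each coarse cell's value is the unweighted arithmetic mean of its member
#' fine cells, per day and per variable (a latitude-weighted mean is
#' available but off by default).
#'
#' @param cube a [climate_cube].
#' @param target target cell size in degrees; must be an integer multiple of
#'   the source cell size.
#' @param lat_weighted if `TRUE`, weight member cells by `cos(latitude)`.
#' @return A coarser [climate_cube].
#' @export
aggregate_grid <- function(cube, target, lat_weighted = FALSE) {
  src <- cube$res
  f <- target / src
  if (abs(f - round(f)) > 1e-8)
    stop("target cell size must be an integer multiple of the source size",
         call. = FALSE)
  f <- as.integer(round(f))
  if (f == 1L) return(cube)
  nlat <- length(cube$lat); nlon <- length(cube$lon)
  if (nlat %% f != 0 || nlon %% f != 0)
    stop("grid extent is not divisible by the aggregation factor",
         call. = FALSE)
  gi <- rep(seq_len(nlat %/% f), each = f)   # coarse row of each fine row
  gj <- rep(seq_len(nlon %/% f), each = f)
  w <- if (lat_weighted) cos(cube$lat * pi / 180) else rep(1, nlat)
  agg <- function(x) {
    if (is.null(x)) return(NULL)
    nt <- dim(x)[3]
    out <- array(NA_real_, c(nlat %/% f, nlon %/% f, nt))
    for (ci in seq_len(nlat %/% f)) for (cj in seq_len(nlon %/% f)) {
      ii <- which(gi == ci); jj <- which(gj == cj)
      wij <- rep(w[ii], times = length(jj))
      sub <- x[ii, jj, , drop = FALSE]
      m <- matrix(sub, nrow = length(ii) * length(jj), ncol = nt)
      out[ci, cj, ] <- colSums(m * wij) / sum(wij)
    }
    out
  }
  newlat <- vapply(split(cube$lat, gi), mean, 0)
  newlon <- vapply(split(cube$lon, gj), mean, 0)
  climate_cube(newlat, newlon, cube$dates,
               tasmax = agg(cube$tasmax), pr = agg(cube$pr),
               swe = agg(cube$swe), prsn = agg(cube$prsn),
               meta = c(cube$meta, list(aggregated_from_deg = src)))
}

#' Subset a cube to a lat/lon box
#'
#' @param cube a [climate_cube].
#' @param box named list or vector with `lat_min`, `lat_max`, `lon_min`,
#'   `lon_max` (degrees, cell centres inside the box are kept).
#' @return A [climate_cube] restricted to the box.
#' @export
subset_cube <- function(cube, box) {
  box <- as.list(box)
  ii <- which(cube$lat >= box$lat_min & cube$lat <= box$lat_max)
  jj <- which(cube$lon >= box$lon_min & cube$lon <= box$lon_max)
  if (!length(ii) || !length(jj)) stop("box contains no grid cells",
                                       call. = FALSE)
  take <- function(x) if (is.null(x)) NULL else x[ii, jj, , drop = FALSE]
  climate_cube(cube$lat[ii], cube$lon[jj], cube$dates,
               tasmax = take(cube$tasmax), pr = take(cube$pr),
               swe = take(cube$swe), prsn = take(cube$prsn),
               meta = cube$meta)
}

#' Axis-aligned boxes for the Arctic regions of special interest
#'
#' Approximate lat/lon bounding boxes for the four regions most prevalent in
#' the literature on biotic impacts of winter extreme events.
#' @return Named list of boxes (`lat_min`, `lat_max`, `lon_min`, `lon_max`).
#' @export
arctic_regions <- function() {
  list(
    northern_alaska = list(lat_min = 68, lat_max = 71.5,
                           lon_min = -167, lon_max = -140),
    northern_fennoscandia = list(lat_min = 68, lat_max = 71.5,
                                 lon_min = 18, lon_max = 31),
    svalbard = list(lat_min = 76, lat_max = 81, lon_min = 10, lon_max = 34),
    yamal = list(lat_min = 66, lat_max = 73, lon_min = 66, lon_max = 82)
  )
}

#' Write a climate cube as plain-text CSV
#'
#' Long-format gridded exchange layout: one row per cell-day with columns
#' `lat`, `lon`, `date` and one column per variable (CF-like names `tasmax`,
#' `pr`, `swe`, `prsn`). Values are written with 17 significant digits so a
#' write/read round trip reproduces the doubles bit-identically.
#'
#' @param cube a [climate_cube].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  vars <- cube_vars(cube)
  nlat <- length(cube$lat); nlon <- length(cube$lon); nt <- length(cube$dates)
  df <- data.frame(
    lat = rep(cube$lat, times = nlon * nt),
    lon = rep(rep(cube$lon, each = nlat), times = nt),
    date = rep(cube$dates, each = nlat * nlon)
  )
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  out <- cbind(lat = fmt(df$lat), lon = fmt(df$lon),
               date = format(df$date))
  for (v in vars) out <- cbind(out, fmt(as.vector(cube[[v]])))
  colnames(out) <- c("lat", "lon", "date", vars)
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a climate cube from the CSV gridded layout
#'
#' Units are normalized on read: temperature in degrees C, rain in mm/day,
#' snow in mm SWE. ERA5-style snow depth in metres of water equivalent is
#' converted here (never in detection logic).
#'
#' @param path file written by [write_cube] (or following its layout).
#' @param snow_unit `"mm"` (default) or `"m"`; with `"m"`, `swe` and `prsn`
#'   are multiplied by 1000 on read.
#' @return A [climate_cube].
#' @export
read_cube <- function(path, snow_unit = c("mm", "m")) {
  snow_unit <- match.arg(snow_unit)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lat", "lon", "date")
  if (!all(need %in% names(df)))
    stop("cube file is missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  dates <- sort(unique(as.Date(df$date)))
  nlat <- length(lat); nlon <- length(lon); nt <- length(dates)
  if (nrow(df) != nlat * nlon * nt)
    stop("cube file is incomplete or corrupted: expected ",
         nlat * nlon * nt, " rows, found ", nrow(df), call. = FALSE)
  ii <- match(df$lat, lat); jj <- match(df$lon, lon)
  tt <- match(as.Date(df$date), dates)
  idx <- cbind(ii, jj, tt)
  get <- function(v, scale = 1) {
    if (!v %in% names(df)) return(NULL)
    a <- array(NA_real_, c(nlat, nlon, nt))
    a[idx] <- df[[v]] * scale
    a
  }
  s <- if (snow_unit == "m") 1000 else 1
  climate_cube(lat, lon, dates,
               tasmax = get("tasmax"), pr = get("pr"),
               swe = get("swe", s), prsn = get("prsn", s),
               meta = list(source = path, snow_unit_in = snow_unit))
}
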