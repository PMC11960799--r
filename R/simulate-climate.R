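#' Configuration for the synthetic climate-field generator
#'
#' Defines a seeded generative model for daily gridded Arctic climate fields:
#' daily maximum temperature is a cell-wise seasonal cycle plus a secular
#' linear trend plus AR(1) noise; precipitation occurs on random days with
#' gamma-distributed amounts and falls as snow on cold days; snowpack follows
#' a simple accumulate-when-cold, melt-when-warm bucket.
#'
#' @param lat_range,lon_range length-2 numeric, grid extents in degrees.
#' @param res cell size in degrees; must divide both extents evenly.
#' @param years length-2 integer, first and last calendar year simulated
#'   (whole years, Jan 1 to Dec 31).
#' @param t_mean annual-mean daily maximum temperature (degrees C) at the
#'   reference latitude `lat_ref`.
#' @param lat_gradient cooling per degree latitude north of `lat_ref`
#'   (degrees C per degree).
#' @param lat_ref reference latitude for `t_mean`.
#' @param amplitude seasonal cycle semi-amplitude (degrees C); the cycle
#'   peaks in mid July (day of year 196).
#' @param trend secular trend on tasmax, degrees C per year.
#' @param ar1 lag-1 autocorrelation of the temperature noise, in [0, 1).
#' @param noise_sd innovation standard deviation of the AR(1) noise
#'   (degrees C); the stationary SD is `noise_sd / sqrt(1 - ar1^2)`.
#' @param rain_prob per-day precipitation occurrence probability, in [0, 1].
#' @param rain_shape,rain_scale gamma parameters of daily precipitation
#'   amounts (mm).
#' @param snow_temp temperature (degrees C) at or below which precipitation
#'   falls as snow.
#' @param melt_rate snowpack melt, mm SWE per degree C above 0 per day.
#' @param seed integer random seed; split internally into per-field
#'   substreams so that adding a field does not perturb earlier fields.
#' @return A list of class `climate_sim_config`.
#' @export
climate_sim_config <- function(lat_range = c(66, 70), lon_range = c(20, 24),
                               res = 1, years = c(1950, 1980),
                               t_mean = -5, lat_gradient = 0.5, lat_ref = 66,
                               amplitude = 12, trend = 0.06,
                               ar1 = 0.7, noise_sd = 3,
                               rain_prob = 0.3, rain_shape = 0.8,
                               rain_scale = 3,
                               snow_temp = 0, melt_rate = 2.5,
                               seed = 1L) {
  for (nm in c("lat_range", "lon_range", "years"))
    if (length(get(nm)) != 2 || diff(get(nm)) < 0)
      stop("invalid '", nm, "': need increasing length-2 range", call. = FALSE)
  if (res <= 0) stop("invalid 'res': must be > 0", call. = FALSE)
  for (nm in c("lat_range", "lon_range")) {
    ext <- diff(get(nm))
    if (ext > 0 && abs(ext / res - round(ext / res)) > 1e-8)
      stop("invalid '", nm, "': cell size must divide the extent evenly",
           call. = FALSE)
  }
  if (ar1 < 0 || ar1 >= 1)
    stop("invalid 'ar1': must be in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("invalid 'noise_sd': must be >= 0", call. = FALSE)
  if (rain_prob < 0 || rain_prob > 1)
    stop("invalid 'rain_prob': must be in [0, 1]", call. = FALSE)
  if (rain_shape <= 0 || rain_scale <= 0)
    stop("invalid rain distribution parameters: must be > 0", call. = FALSE)
  if (melt_rate < 0) stop("invalid 'melt_rate': must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "climate_sim_config")
}

cell_centres <- function(range, res) {
  if (diff(range) == 0) return(mean(range))
  seq(range[1] + res / 2, range[2] - res / 2, by = res)
}

#' Simulate a daily gridded climate cube
#'
#' Generates `tasmax` (degrees C), `pr` (rain, mm/day), `prsn` (snowfall,
#' mm SWE/day) and `swe` (snowpack, mm SWE) per cell and day under the model
#' in [climate_sim_config]. The recorded `swe` for a day is the snowpack
#' after that day's snowfall but before its melt, so rain falling on an
#' existing pack sees the pack. Reproducible under a fixed seed.
#'
#' @param config a [climate_sim_config].
#' @return A [climate_cube] with all four variables.
#' @export
simulate_climate <- function(config) {
  stopifnot(inherits(config, "climate_sim_config"))
  lat <- cell_centres(config$lat_range, config$res)
  lon <- cell_centres(config$lon_range, config$res)
  dates <- seq(as.Date(sprintf("%d-01-01", config$years[1])),
               as.Date(sprintf("%d-12-31", config$years[2])), by = "day")
  nlat <- length(lat); nlon <- length(lon); nt <- length(dates)
  ncell <- nlat * nlon
  doy <- as.integer(format(dates, "%j"))
  yr <- as.integer(format(dates, "%Y"))

  # deterministic components of tasmax
  cyc <- config$t_mean + config$amplitude *
    cos(2 * pi * (doy - 196) / 365.25)               # peak mid July
  trend_t <- config$trend * (yr - config$years[1])
  offs <- -config$lat_gradient * (lat - config$lat_ref)  # per-lat offset

  # substream 1: temperature noise
  set.seed(config$seed)
  if (config$noise_sd > 0) {
    innov <- matrix(stats::rnorm(ncell * nt, sd = config$noise_sd),
                    nrow = nt, ncol = ncell)
    noise <- apply(innov, 2, function(e)
      as.numeric(stats::filter(e, config$ar1, method = "recursive")))
  } else {
    noise <- matrix(0, nt, ncell)
  }
  base <- cyc + trend_t                               # length nt
  off_cell <- rep(offs, times = nlon)                 # per cell (lat fastest)
  tas <- noise + matrix(base, nt, ncell) +
    matrix(off_cell, nt, ncell, byrow = TRUE)

  # substream 2: precipitation occurrence and amount
  set.seed(config$seed + 1L)
  occ <- matrix(stats::runif(ncell * nt) < config$rain_prob, nt, ncell)
  amt <- matrix(stats::rgamma(ncell * nt, shape = config$rain_shape,
                              scale = config$rain_scale), nt, ncell)
  amt[!occ] <- 0

  # snow bucket: accumulate when cold, melt when warm
  rain <- matrix(0, nt, ncell)
  snowfall <- matrix(0, nt, ncell)
  swe <- matrix(0, nt, ncell)
  pack <- rep(0, ncell)
  for (t in seq_len(nt)) {
    cold <- tas[t, ] <= config$snow_temp
    snowfall[t, ] <- ifelse(cold, amt[t, ], 0)
    rain[t, ] <- ifelse(cold, 0, amt[t, ])
    pack <- pack + snowfall[t, ]
    swe[t, ] <- pack                                   # pre-melt snapshot
    melt <- config$melt_rate * pmax(0, tas[t, ] - config$snow_temp)
    pack <- pmax(0, pack - melt)
  }

  shape3 <- function(m) array(t(m), dim = c(nlat, nlon, nt))
  climate_cube(lat, lon, dates,
               tasmax = shape3(tas), pr = shape3(rain),
               swe = shape3(swe), prsn = shape3(snowfall),
               meta = list(generator = "simulate_climate",
                           seed = config$seed,
                           trend_per_year = config$trend))
}
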