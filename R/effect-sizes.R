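#' Standardized mean difference with heteroscedastic variances (SMDH)
#'
#' Hedges-type standardized mean difference allowing the two groups'
#' population variances to differ. The point estimate is
#' `J(m) * (mean_r - mean_c) / s'` with `s' = sqrt((SD_c^2 + SD_r^2)/2)`,
#' `m = n_c + n_r - 2`, and `J(m) = gamma(m/2) / (sqrt(m/2) gamma((m-1)/2))`
#' the exact small-sample bias correction. The large-sample sampling
#' variance is
#' `d^2 (SD_c^4/(n_c-1) + SD_r^4/(n_r-1)) / (8 s'^4)
#'   + (SD_c^2/(n_c-1) + SD_r^2/(n_r-1)) / s'^2`
#' with `d` the bias-corrected estimate. All arguments are vectorized.
#'
#' @param n_c,mean_c,sd_c control-group size (>= 2), mean and SD.
#' @param n_r,mean_r,sd_r response-group size (>= 2), mean and SD.
#' @return A data frame with columns `yi` (SMDH, response minus control)
#'   and `vi` (sampling variance).
#' @export
smdh <- function(n_c, mean_c, sd_c, n_r, mean_r, sd_r) {
  if (any(n_c < 2 | n_r < 2))
    stop("both groups need n >= 2", call. = FALSE)
  if (any(sd_c < 0 | sd_r < 0)) stop("SDs must be >= 0", call. = FALSE)
  sp2 <- (sd_c^2 + sd_r^2) / 2
  if (any(sp2 == 0))
    stop("both SDs zero: standardized difference undefined", call. = FALSE)
  m <- n_c + n_r - 2
  cm <- exp(lgamma(m / 2) - log(sqrt(m / 2)) - lgamma((m - 1) / 2))
  yi <- cm * (mean_r - mean_c) / sqrt(sp2)
  vi <- yi^2 * (sd_c^4 / (n_c - 1) + sd_r^4 / (n_r - 1)) / (8 * sp2^2) +
    (sd_c^2 / (n_c - 1) + sd_r^2 / (n_r - 1)) / sp2
  data.frame(yi = yi, vi = vi)
}

#' Direction flags shipped with the package
#'
#' Editable lookup from response-variable name to a direction flag (+1 when
#' an increase in the response benefits fitness, -1 when it harms it, e.g.
#' winter mortality). Used by [harmonize_direction] so that negative
#' harmonized effect sizes always mean negative fitness impact.
#'
#' @return A data frame with columns `variable`, `flag`.
#' @export
direction_flags <- function() {
  path <- system.file("extdata", "direction-flags.csv",
                      package = "arcwinter")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Harmonize the fitness direction of effect sizes
#'
#' Multiplies each raw SMDH by its direction flag (-1 when an increase in
#' the response mean affects fitness negatively), looked up by response
#' variable name. Records whose variable has no flag are quarantined, not
#' silently passed through. Applying the harmonization twice is detected
#' and refused.
#'
#' @param records data frame with at least `yi` and `response_variable`.
#' @param flags lookup data frame (`variable`, `flag`); defaults to the
#'   shipped [direction_flags] table.
#' @return A list: `records` (harmonized; flag stored in column
#'   `direction`), `quarantined` (records with unknown variables). The
#'   harmonized data frame carries attribute `direction_applied = TRUE`.
#' @export
harmonize_direction <- function(records, flags = direction_flags()) {
  if (isTRUE(attr(records, "direction_applied")))
    stop("direction harmonization already applied to these records",
         call. = FALSE)
  m <- match(tolower(records$response_variable), tolower(flags$variable))
  unknown <- is.na(m)
  kept <- records[!unknown, , drop = FALSE]
  kept$direction <- flags$flag[m[!unknown]]
  kept$yi <- kept$yi * kept$direction
  attr(kept, "direction_applied") <- TRUE
  list(records = kept, quarantined = records[unknown, , drop = FALSE])
}

#' Derive control/response groups from an observational series
#'
#' Splits annual observations of a fitness-related variable into a
#' "response" (extreme years) and a "control" group. If extreme years are
#' supplied, they are used directly, with the year preceding each extreme
#' year as its control. Otherwise a year counts as extreme when the site's
#' environmental variable exceeds the regional 99th percentile threshold
#' computed over the baseline period in a box around the site; an extreme
#' year is kept only when the immediately preceding year is available as a
#' control. A year never serves as control for two extreme years (the
#' conflict is logged), and an extreme year is never its own control.
#'
#' @param years,values annual observations (numeric vectors, same length).
#' @param extreme_years optional integer vector of known extreme years.
#' @param cube,site for the unlabelled path: a [climate_cube] and the site
#'   `c(lat, lon)`; the environmental variable is the per-season maximum of
#'   `variable` at the site's cell.
#' @param variable cube variable defining "extreme" (default `"tasmax"`).
#' @param baseline baseline period for the regional percentile.
#' @param box_deg side length (degrees) of the region around the site.
#' @param prob percentile (default 0.99).
#' @return A list with `control` and `response` group summaries (`n`,
#'   `mean`, `sd`), the classified `years`, and a `log` of exclusions; or
#'   an error if either group would have fewer than 2 years.
#' @export
derive_groups_from_series <- function(years, values, extreme_years = NULL,
                                      cube = NULL, site = NULL,
                                      variable = "tasmax",
                                      baseline = c(1950, 1980),
                                      box_deg = 5, prob = 0.99) {
  stopifnot(length(years) == length(values))
  o <- order(years); years <- years[o]; values <- values[o]
  log <- character()
  if (is.null(extreme_years)) {
    if (is.null(cube) || is.null(site))
      stop("without labelled extreme years, 'cube' and 'site' are required",
           call. = FALSE)
    box <- list(lat_min = site[1] - box_deg / 2,
                lat_max = site[1] + box_deg / 2,
                lon_min = site[2] - box_deg / 2,
                lon_max = site[2] + box_deg / 2)
    reg <- subset_cube(cube, box)
    lab <- winter_seasons(reg$dates)
    base_idx <- !is.na(lab) & lab %in% period_seasons(baseline)
    thr <- stats::quantile(reg[[variable]][, , base_idx], prob, type = 7,
                           names = FALSE, na.rm = TRUE)
    # site series: per-season maximum of the variable at the nearest cell
    i <- which.min(abs(cube$lat - site[1]))
    j <- which.min(abs(cube$lon - site[2]))
    v <- cube[[variable]][i, j, ]
    site_max <- tapply(v[!is.na(lab)], lab[!is.na(lab)], max, na.rm = TRUE)
    env_years <- as.integer(names(site_max))
    extreme_years <- env_years[site_max > thr]
  }
  is_ext <- years %in% extreme_years
  resp_years <- integer(); ctrl_years <- integer()
  for (yy in years[is_ext]) {
    prev <- yy - 1L
    if (!(prev %in% years)) {
      log <- c(log, sprintf("extreme year %d excluded: no preceding year",
                            yy)); next
    }
    if (prev %in% extreme_years) {
      log <- c(log, sprintf(
        "extreme year %d excluded: preceding year is itself extreme", yy))
      next
    }
    if (prev %in% ctrl_years) {
      log <- c(log, sprintf(
        "extreme year %d excluded: control year %d already used", yy, prev))
      next
    }
    resp_years <- c(resp_years, yy)
    ctrl_years <- c(ctrl_years, prev)
  }
  if (length(resp_years) < 2 || length(ctrl_years) < 2)
    stop("fewer than 2 years per group: no record emitted (",
         paste(log, collapse = "; "), ")", call. = FALSE)
  grp <- function(yy) {
    v <- values[years %in% yy]
    list(n = length(v), mean = mean(v), sd = stats::sd(v))
  }
  list(control = grp(ctrl_years), response = grp(resp_years),
       years = list(control = ctrl_years, response = resp_years),
       log = log)
}

#' Remove outlying effect sizes
#'
#' Standardized residuals are computed under a fitted random-effects
#' overall-mean model: `(yi - mu_hat) / sqrt(vi + tau2_hat)` with `mu_hat`
#' and `tau2_hat` from a single-component REML fit. Records with absolute
#' standardized residual greater than `cut` are removed in one pass (no
#' refit-and-repeat); the policy is idempotent on its own output only in
#' the sense that the single pass is never repeated automatically. A
#' common-effect standardization (`tau2 = 0`) is switchable.
#'
#' @param yi,vi effect sizes and sampling variances.
#' @param cut residual cutoff (default 3).
#' @param model `"random"` (default) or `"common"`.
#' @return A list: `keep` (logical vector), `residuals` (standardized),
#'   `n_removed`, `mu`, `tau2`.
#' @export
remove_outliers <- function(yi, vi, cut = 3, model = c("random", "common")) {
  model <- match.arg(model)
  if (length(yi) < 3) stop("need at least 3 records", call. = FALSE)
  if (model == "random") {
    f <- meta_fit(yi ~ 1, vi = vi, data = data.frame(yi = yi, vi = vi),
                  random = "es")
    mu <- unname(stats::coef(f)); tau2 <- sum(f$sigma2)
  } else {
    w <- 1 / vi
    mu <- sum(w * yi) / sum(w); tau2 <- 0
  }
  z <- (yi - mu) / sqrt(vi + tau2)
  keep <- abs(z) <= cut
  list(keep = keep, residuals = z, n_removed = sum(!keep), mu = mu,
       tau2 = tau2)
}
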