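#' Project biotic impact of changing extreme-event exposure
#'
#' Multiplies the per-cell change in an event metric between two periods
#' (e.g. cumulative winter warming exceedance in degrees C, or total
#' rain-on-snow in mm) by a statistically significant pooled effect size,
#' producing a map of the relative magnitude of projected biotic impact.
#' The projection refuses to run when the pooled effect's confidence
#' interval includes zero. Impacts are relative magnitudes, not precise
#' measurements; the caveat is recorded in the result metadata.
#'
#' @param change data frame with `lat`, `lon`, `change` (metric units), as
#'   produced by differencing two [paired_period_test] period means or any
#'   per-cell change field.
#' @param effect pooled effect: a list/row with `estimate`, `ci.lb`,
#'   `ci.ub` (e.g. one row of a [predict.meta_fit] result plus estimate).
#' @param event_type label stored in the metadata ("warming" or "ros").
#' @return A data frame (`lat`, `lon`, `impact`) of class `projection_map`
#'   with attributes `effect`, `event_type` and `caveat`.
#' @export
project_impacts <- function(change, effect, event_type = "warming") {
  est <- effect$estimate %||% effect$pred
  if (is.null(est)) stop("effect must carry 'estimate' (or 'pred')",
                         call. = FALSE)
  if (effect$ci.lb <= 0 && effect$ci.ub >= 0)
    stop("pooled effect is not statistically significant (CI includes 0): ",
         "projection refused", call. = FALSE)
  out <- data.frame(lat = change$lat, lon = change$lon,
                    impact = change$change * est)
  attr(out, "effect") <- list(estimate = est, ci.lb = effect$ci.lb,
                              ci.ub = effect$ci.ub)
  attr(out, "event_type") <- event_type
  attr(out, "caveat") <- "relative magnitudes; not precise measurements"
  class(out) <- c("projection_map", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-cell period change of a summary variable
#'
#' Convenience: per-cell mean of a summary variable in each period and
#' their difference (B - A).
#'
#' @param summaries output of [annual_summaries].
#' @param period_a,period_b length-2 periods.
#' @param variable summary column (default `"total"`).
#' @return Data frame `lat`, `lon`, `change`.
#' @export
period_change <- function(summaries, period_a, period_b,
                          variable = "total") {
  pc <- paired_period_test(summaries, period_a, period_b, variable)
  data.frame(lat = pc$cells$lat, lon = pc$cells$lon,
             change = pc$cells$mean_b - pc$cells$mean_a)
}

#' Research-effort coverage gaps
#'
#' Compares projected impact magnitude against study coverage: per region
#' box, the mean absolute projected impact and the number of study
#' locations falling inside, sorted so the largest-impact, least-studied
#' regions top the report.
#'
#' @param projection a [project_impacts] result.
#' @param study_locations data frame with `lat`, `lon` (may be empty).
#' @param regions named list of boxes (default [arctic_regions]).
#' @return Data frame `region`, `mean_abs_impact`, `n_studies`, sorted by
#'   decreasing impact then increasing study count.
#' @export
coverage_gap <- function(projection, study_locations,
                         regions = arctic_regions()) {
  rows <- lapply(names(regions), function(nm) {
    b <- regions[[nm]]
    inr <- projection$lat >= b$lat_min & projection$lat <= b$lat_max &
      projection$lon >= b$lon_min & projection$lon <= b$lon_max
    ns <- if (nrow(study_locations) == 0) 0L else
      sum(study_locations$lat >= b$lat_min &
            study_locations$lat <= b$lat_max &
            study_locations$lon >= b$lon_min &
            study_locations$lon <= b$lon_max)
    data.frame(region = nm,
               mean_abs_impact = if (any(inr))
                 mean(abs(projection$impact[inr]), na.rm = TRUE)
               else NA_real_,
               n_studies = ns)
  })
  out <- do.call(rbind, rows)
  out[order(-out$mean_abs_impact, out$n_studies), , drop = FALSE]
}
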