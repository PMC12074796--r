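#' Annual rate of change in sea surface temperature
#'
#' Ordinary least-squares slope of annual SST on calendar year; the
#' warming-trend predictor of the path model, in degrees C per year.
#'
#' @param sst Numeric vector of annual SST values.
#' @param years Calendar years the values belong to (defaults to
#'   consecutive years).
#' @return The regression slope.
#' @export
sst_trend <- function(sst, years = seq_along(sst)) {
  if (length(sst) < 3L) stop("need at least 3 years to estimate a trend")
  if (length(years) != length(sst)) stop("'years' and 'sst' lengths differ")
  unname(stats::coef(stats::lm(sst ~ years))[2L])
}

#' Coefficient of variation of an annual series
#'
#' Sample standard deviation divided by the mean; the interannual
#' variability predictors (`cv_sst`, `cv_chl`) of the path model.
#'
#' @param x Numeric series with positive mean.
#' @return `sd(x) / mean(x)`.
#' @export
cv_series <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m <= 0) {
    stop("coefficient of variation requires a positive mean")
  }
  stats::sd(x) / m
}

#' Summarize per-site abiotic series into path-model predictors
#'
#' Reduces each site profile to the predictors entering the path model:
#' temporal mean SST, the SST warming trend, interannual CVs of SST and
#' chlorophyll a, human gravity, site depth and the number of surveyed
#' years (a control for the amount of gap-filled data). Mean annual
#' chlorophyll and its linear trend are computed as well but excluded from
#' the default output because they track SST closely; set
#' `keep_chl_extras = TRUE` to retain them.
#'
#' @param sites List of site profiles from [generate_sites()] (or any list
#'   with fields `site_id`, `mean_sst`, `sst_series`, `chl_series`,
#'   `gravity`, `site_depth`, `surveyed_years`, `years`).
#' @param keep_chl_extras Also return `mean_chl` and `chl_change`.
#' @return Data frame, one row per site (an `AbioticSummary`).
#' @export
abiotic_summary <- function(sites, keep_chl_extras = FALSE) {
  rows <- lapply(sites, function(s) {
    yrs <- if (!is.null(s$years)) s$years else seq_along(s$sst_series)
    out <- data.frame(
      site_id = s$site_id,
      mean_sst = mean(s$sst_series),
      sst_change = sst_trend(s$sst_series, yrs),
      cv_sst = cv_series(s$sst_series),
      cv_chl = cv_series(s$chl_series),
      gravity = s$gravity,
      site_depth = s$site_depth,
      n_years = length(s$surveyed_years)
    )
    if (keep_chl_extras) {
      out$mean_chl <- mean(s$chl_series)
      out$chl_change <- sst_trend(s$chl_series, yrs)
    }
    out
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
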