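#' Run the full stability analysis on survey-style data
#'
#' Composes the whole pipeline: block aggregation, length-weight biomass,
#' per-site community matrices, the minimum-years site filter, half-minimum
#' zero replacement, linear gap interpolation, the stability partition, the
#' four functional-diversity facets, abiotic summaries, and the merged
#' site-level analysis table with the variables the path model expects
#' (`species_stability` and `community_stability` on the log scale,
#' `asynchrony` as `1 - phi`).
#'
#' @param surveys Long-format survey table (e.g. from
#'   [simulate_surveys()]`$surveys`).
#' @param traits Species trait table.
#' @param sites List of site profiles (for the abiotic summaries).
#' @param min_years Minimum surveyed years per site.
#' @param window Study year window.
#' @param quantile Distinct-species quantile for the residualized count.
#' @return List with `matrices` (gap-filled community matrices of the
#'   retained sites), `stability` (per-site partition table), `facets`,
#'   `abiotic` and `data` (the merged analysis table).
#' @export
reef_pipeline <- function(surveys, traits, sites, min_years = 7L,
                          window = c(2008L, 2021L), quantile = 0.25) {
  agg <- aggregate_blocks(surveys)
  bio <- biomass_from_counts(agg, traits)
  mats <- build_community_matrices(bio, window = window)
  mats <- filter_sites(mats, min_years = min_years, window = window)
  if (!length(mats)) stop("no site passes the minimum-years filter")
  mats <- lapply(mats, impute_zero_records)
  mats <- lapply(mats, interpolate_missing_years)

  stab_rows <- lapply(mats, function(cm) {
    sp <- decompose_stability(cm$biomass)
    data.frame(
      site_id = cm$site_id,
      s_c = sp$s_c, inv_cv_sp = sp$inv_cv_sp, phi = sp$phi,
      asynchrony = sp$asynchrony,
      community_stability = sp$log_s_c,
      species_stability = sp$log_inv_cv_sp
    )
  })
  stability <- do.call(rbind, c(stab_rows, list(make.row.names = FALSE)))

  facets <- facet_table(mats, traits, quantile = quantile)
  abiotic <- abiotic_summary(sites)
  dat <- merge(merge(stability, facets, by = "site_id"),
               abiotic, by = "site_id")
  list(matrices = mats, stability = stability, facets = facets,
       abiotic = abiotic, data = dat)
}
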