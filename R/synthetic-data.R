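#' Generator settings for the synthetic survey simulator
#'
#' Bundles every tunable of the synthetic reef-survey generator. Defaults
#' emulate the structure of a continental-scale shallow-reef monitoring
#' programme: a mean-SST gradient spanning 13.9-25.4 degC, a 14-year
#' window (2008-2021) with a mean of roughly 9 surveyed years per site,
#' per-site SST warming trends of 0.1 +/- 0.2 degC per year, 1-6 transects
#' per site, species-rich warm-water communities, and lognormal AR(1)
#' species biomass dynamics whose variance responds to human gravity and
#' to the warming trend through species' trophic level.
#'
#' @param window Closed study year range.
#' @param sst_span Range of site mean SST (degC), low then high.
#' @param sst_trend_mean,sst_trend_sd Across-site distribution of the
#'   linear SST trend (degC per year).
#' @param sst_noise_sd Interannual SST noise around the trend (degC).
#' @param chl_meanlog,chl_sst_beta,chl_noise_sdlog Site mean chlorophyll a
#'   (mg m-3) is lognormal with log-mean
#'   `chl_meanlog + chl_sst_beta * z(mean_sst)`, so it tracks SST.
#' @param chl_cv Target interannual CV of the chlorophyll series.
#' @param gravity_meanlog,gravity_sdlog Lognormal human-gravity index.
#' @param depth_meanlog,depth_sdlog Lognormal site depth (m).
#' @param gap_prob Probability that a given year goes unsurveyed
#'   (before the `min_years` floor is enforced).
#' @param min_years Minimum surveyed years per site.
#' @param transect_range Range (inclusive) of transects per site.
#' @param base_richness Expected site richness at the gradient midpoint.
#' @param richness_sst Log-scale effect of standardized mean SST on site
#'   richness (positive: tropical sites are richer).
#' @param trophic_optimum_cor Correlation between a species' thermal
#'   optimum and its trophic level (negative: cold-water communities have
#'   higher mean trophic level).
#' @param niche_breadth Thermal niche breadth (degC) for composition
#'   turnover along the gradient.
#' @param base_abundance Expected per-block count of an average species.
#' @param abundance_length_beta Log-scale effect of standardized log
#'   maximum length on abundance (negative: large fish are rarer).
#' @param abundance_sdlog Species-by-site lognormal abundance scatter.
#' @param base_sigma Baseline standard deviation of log species biomass
#'   (controls species-level CV).
#' @param sigma_sdlog Species-level lognormal scatter of that sd.
#' @param ar_rho AR(1) autocorrelation of log biomass.
#' @param effect_gravity_cv Effect of standardized gravity on log species
#'   biomass sd, scaled by the species' trophic score (0 at trophic level
#'   2, 1 at 4.6): human pressure destabilizes high-trophic species.
#' @param effect_warming_cv Effect of the standardized SST trend on log
#'   species biomass sd, scaled by one minus the trophic score: warming
#'   destabilizes low-trophic species.
#' @param observation `"poisson"` for Poisson count observation;
#'   `"none"` for deterministic quantized counts (exact round-trip with
#'   the latent biomass ledger).
#' @param size_bins Total-length bin boundaries (cm), geometric by default.
#' @param length_sdlog Within-species spread of individual lengths around
#'   0.65 x maximum length, on the log scale.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(window = c(2008L, 2021L),
                       sst_span = c(13.9, 25.4),
                       sst_trend_mean = 0.1, sst_trend_sd = 0.2,
                       sst_noise_sd = 0.35,
                       chl_meanlog = log(0.4), chl_sst_beta = -0.7,
                       chl_noise_sdlog = 0.45, chl_cv = 0.25,
                       gravity_meanlog = 0, gravity_sdlog = 1,
                       depth_meanlog = log(6), depth_sdlog = 0.4,
                       gap_prob = 0.36, min_years = 7L,
                       transect_range = c(1L, 6L),
                       base_richness = 40, richness_sst = 0.4,
                       trophic_optimum_cor = -0.5, niche_breadth = 5,
                       base_abundance = 8, abundance_length_beta = -0.7,
                       abundance_sdlog = 0.8,
                       base_sigma = 0.35, sigma_sdlog = 0.15,
                       ar_rho = 0.3,
                       effect_gravity_cv = 0.35,
                       effect_warming_cv = 0.35,
                       observation = c("poisson", "none"),
                       size_bins = 2.5 * 2^(0:7),
                       length_sdlog = 0.25) {
  if (sst_span[1L] >= sst_span[2L]) {
    stop("invalid 'sst_span': lower limit must be below upper limit")
  }
  if (gap_prob < 0 || gap_prob >= 1) stop("'gap_prob' must be in [0, 1)")
  cfg <- as.list(environment())
  cfg$observation <- match.arg(observation)
  structure(cfg, class = "sim_config")
}

#' Generate a species pool with correlated traits
#'
#' Draws a trait table of `n_species` reef-fish-like species: lognormal
#' maximum length, a growth coefficient that declines with length (slow
#' life histories in large fish), a trophic level in \[2, 4.6\] positively
#' correlated with log length, lognormal maximum depth, and length-weight
#' coefficients with exponent near 3.
#'
#' @param n_species Number of species (>= 2).
#' @param seed Integer seed.
#' @return Data frame (`TraitTable`) with columns `species_id`,
#'   `max_length` (cm), `growth_coeff` (1/year), `trophic_level`,
#'   `max_depth` (m), `lw_a`, `lw_b`.
#' @export
generate_species_pool <- function(n_species, seed = 1L) {
  if (n_species < 2L) stop("'n_species' must be at least 2")
  set.seed(seed)
  z_len <- stats::rnorm(n_species)
  max_length <- exp(log(30) + 0.8 * z_len)
  trophic <- pmin(pmax(3.2 + 0.45 * z_len + 0.4 * stats::rnorm(n_species),
                       2), 4.6)
  growth <- exp(log(0.4) - 0.45 * z_len + 0.3 * stats::rnorm(n_species))
  max_depth <- exp(log(20) + 0.4 * z_len + 0.5 * stats::rnorm(n_species))
  lw_a <- exp(log(0.012) + 0.25 * stats::rnorm(n_species))
  lw_b <- stats::rnorm(n_species, 3, 0.08)
  data.frame(
    species_id = sprintf("sp%04d", seq_len(n_species)),
    max_length = max_length,
    growth_coeff = growth,
    trophic_level = trophic,
    max_depth = max_depth,
    lw_a = lw_a,
    lw_b = lw_b,
    stringsAsFactors = FALSE
  )
}

#' Generate site profiles along the SST gradient
#'
#' Each site gets a mean SST drawn uniformly over the configured span, an
#' annual SST series with a site-specific linear trend plus noise, a
#' chlorophyll a series whose mean tracks SST, a lognormal human-gravity
#' index and site depth, and a set of surveyed years sampled with the
#' configured gap probability subject to the minimum-years floor.
#'
#' @param n_sites Number of sites (>= 1).
#' @param seed Integer seed.
#' @param config A [sim_config()] list.
#' @return List of site profiles (`SiteProfile`): each a list with
#'   `site_id`, `mean_sst`, `sst_trend_true`, `sst_series`, `chl_series`,
#'   `gravity`, `site_depth`, `surveyed_years`, `years`.
#' @export
generate_sites <- function(n_sites, seed = 1L, config = sim_config()) {
  if (n_sites < 1L) stop("'n_sites' must be at least 1")
  set.seed(seed)
  cfg <- config
  years <- seq.int(cfg$window[1L], cfg$window[2L])
  ny <- length(years)
  mean_sst <- stats::runif(n_sites, cfg$sst_span[1L], cfg$sst_span[2L])
  z_sst <- if (n_sites > 1L) as.vector(scale(mean_sst)) else 0
  trend <- stats::rnorm(n_sites, cfg$sst_trend_mean, cfg$sst_trend_sd)
  mean_chl <- exp(cfg$chl_meanlog + cfg$chl_sst_beta * z_sst +
                    cfg$chl_noise_sdlog * stats::rnorm(n_sites))
  chl_sdlog <- sqrt(log(1 + cfg$chl_cv^2))
  lapply(seq_len(n_sites), function(s) {
    centred <- years - mean(years)
    sst_series <- mean_sst[s] + trend[s] * centred +
      stats::rnorm(ny, 0, cfg$sst_noise_sd)
    chl_series <- mean_chl[s] * exp(stats::rnorm(ny, 0, chl_sdlog) -
                                      chl_sdlog^2 / 2)
    surveyed <- years[stats::runif(ny) >= cfg$gap_prob]
    if (length(surveyed) < cfg$min_years) {
      extra <- sample(setdiff(years, surveyed),
                      cfg$min_years - length(surveyed))
      surveyed <- sort(c(surveyed, extra))
    }
    list(
      site_id = sprintf("site%03d", s),
      mean_sst = mean_sst[s],
      sst_trend_true = trend[s],
      sst_series = sst_series,
      chl_series = chl_series,
      gravity = stats::rlnorm(1, cfg$gravity_meanlog, cfg$gravity_sdlog),
      site_depth = stats::rlnorm(1, cfg$depth_meanlog, cfg$depth_sdlog),
      surveyed_years = surveyed,
      years = years
    )
  })
}

#' The generator's ledger of ground-truth effects
#'
#' Records every nonzero generative effect of [simulate_surveys()] as a
#' signed magnitude, including trait-mediation rules, so parameter-recovery
#' tests know what the data were built to contain.
#'
#' @param config A [sim_config()].
#' @return Data frame of class `"truth_ledger"` with columns `driver`,
#'   `response`, `moderator` (`"none"` for unmoderated effects) and
#'   `effect`.
#' @export
truth_ledger <- function(config = sim_config()) {
  entries <- data.frame(
    driver = c("gravity", "sst_change", "mean_sst", "mean_sst"),
    response = c("species_cv", "species_cv", "richness", "thermal_optimum"),
    moderator = c("trophic_high", "trophic_low", "none", "trophic_level"),
    effect = c(config$effect_gravity_cv, config$effect_warming_cv,
               config$richness_sst, config$trophic_optimum_cor),
    stringsAsFactors = FALSE
  )
  entries <- entries[entries$effect != 0, , drop = FALSE]
  rownames(entries) <- NULL
  class(entries) <- c("truth_ledger", "data.frame")
  entries
}

#' @export
print.truth_ledger <- function(x, ...) {
  cat("Generator truth ledger:", nrow(x), "nonzero effects\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Simulate survey-style community time series
#'
#' Draws which species occur at each site (richness grows with mean SST;
#' composition turns over along the gradient through trait-linked thermal
#' optima), gives every species-site a lognormal AR(1) biomass trajectory
#' whose variance responds to human gravity and the warming trend through
#' trophic level, and observes the trajectories as size-structured counts
#' in blocks and transects. With Poisson observation, sparse species yield
#' genuine zero-detection years.
#'
#' @param traits Trait table from [generate_species_pool()].
#' @param sites List of site profiles from [generate_sites()].
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List with components:
#'   * `surveys`: long-format survey table (`site_id`, `year`,
#'     `transect_id`, `block_id`, `species_id`, `size_class`, `abundance`),
#'     surveyed years only, positive counts only;
#'   * `truth`: the [truth_ledger()];
#'   * `latent`: per-site species x year matrices of latent biomass
#'     (transect-average scale, every window year, before observation);
#'   * `config`: the settings used.
#' @export
simulate_surveys <- function(traits, sites, config = sim_config(),
                             seed = 1L) {
  if (length(sites) == 0L) stop("'sites' must contain at least one site")
  cfg <- config
  set.seed(seed)
  n_sp <- nrow(traits)
  years <- sites[[1L]]$years
  ny <- length(years)

  z_troph <- as.vector(scale(traits$trophic_level))
  if (anyNA(z_troph)) z_troph <- rep(0, n_sp)
  troph_score <- (traits$trophic_level - 2) / 2.6
  z_len <- as.vector(scale(log(traits$max_length)))
  if (anyNA(z_len)) z_len <- rep(0, n_sp)

  # thermal optima: warm-skewed, negatively correlated with trophic level
  rho_opt <- cfg$trophic_optimum_cor
  opt_raw <- rho_opt * z_troph +
    sqrt(max(0, 1 - rho_opt^2)) * stats::rnorm(n_sp)
  span <- cfg$sst_span
  optimum <- span[1L] - 2 + (span[2L] - span[1L] + 4) *
    stats::pnorm(opt_raw + 0.4)

  # size-class allocation around a species-specific mean length
  mids <- (cfg$size_bins[-length(cfg$size_bins)] + cfg$size_bins[-1L]) / 2
  bin_probs <- lapply(seq_len(n_sp), function(i) {
    lbar <- 0.65 * traits$max_length[i]
    p <- diff(stats::plnorm(cfg$size_bins, log(lbar), cfg$length_sdlog))
    p[p < 0.01] <- 0
    if (sum(p) == 0) p[which.min(abs(mids - lbar))] <- 1
    p / sum(p)
  })
  # per-individual weight by bin, for the latent biomass ledger
  bin_w <- lapply(seq_len(n_sp), function(i) {
    traits$lw_a[i] * mids^traits$lw_b[i]
  })

  mean_sst <- vapply(sites, `[[`, numeric(1), "mean_sst")
  gravity <- vapply(sites, `[[`, numeric(1), "gravity")
  trend <- vapply(sites, `[[`, numeric(1), "sst_trend_true")
  z_site <- function(x) {
    if (length(x) > 1L && stats::sd(x) > 0) as.vector(scale(x)) else
      rep(0, length(x))
  }
  z_sst <- z_site(mean_sst)
  z_grav <- z_site(log1p(gravity))
  z_trend <- z_site(trend)

  quantize <- cfg$observation == "none"
  surveys_by_site <- vector("list", length(sites))
  latent <- vector("list", length(sites))
  names(latent) <- vapply(sites, `[[`, "", "site_id")

  for (s in seq_along(sites)) {
    site <- sites[[s]]
    s_rich <- max(2L, min(n_sp, round(cfg$base_richness *
                                        exp(cfg$richness_sst * z_sst[s]))))
    w_thermal <- exp(-0.5 * ((site$mean_sst - optimum) / cfg$niche_breadth)^2)
    present <- sample.int(n_sp, s_rich, prob = w_thermal + 1e-6)

    n_tr <- if (cfg$transect_range[1L] == cfg$transect_range[2L]) {
      cfg$transect_range[1L]
    } else {
      sample(seq.int(cfg$transect_range[1L], cfg$transect_range[2L]), 1L)
    }

    # species-site log-biomass sd: trait-mediated pressure responses
    log_sigma <- log(cfg$base_sigma) +
      cfg$effect_gravity_cv * z_grav[s] * troph_score[present] +
      cfg$effect_warming_cv * z_trend[s] * (1 - troph_score[present]) +
      stats::rnorm(s_rich, 0, cfg$sigma_sdlog)
    sigma <- exp(log_sigma)

    # mean per-block abundance: rarer for large-bodied species
    nbar <- exp(log(cfg$base_abundance) +
                  cfg$abundance_length_beta * z_len[present] +
                  stats::rnorm(s_rich, 0, cfg$abundance_sdlog))

    # lognormal AR(1) abundance trajectories, stationary sd = sigma
    x <- matrix(0, s_rich, ny)
    x[, 1L] <- stats::rnorm(s_rich, 0, sigma)
    if (ny > 1L) {
      innov_sd <- sigma * sqrt(1 - cfg$ar_rho^2)
      for (t in 2:ny) {
        x[, t] <- cfg$ar_rho * x[, t - 1L] + stats::rnorm(s_rich, 0, innov_sd)
      }
    }
    n_latent <- nbar * exp(x - sigma^2 / 2)  # expected count per block

    if (quantize) {
      # one representative bin, whole individuals: exact reconstruction
      rep_bin <- vapply(bin_probs[present], which.max, integer(1))
      n_latent <- round(n_latent)
      w_rep <- vapply(seq_len(s_rich),
                      function(i) bin_w[[present[i]]][rep_bin[i]], numeric(1))
      lat <- 2 * n_latent * w_rep
    } else {
      w_exp <- vapply(seq_len(s_rich), function(i) {
        sum(bin_probs[[present[i]]] * bin_w[[present[i]]])
      }, numeric(1))
      lat <- 2 * n_latent * w_exp
    }
    dimnames(lat) <- list(traits$species_id[present], years)
    latent[[s]] <- lat

    sy <- site$surveyed_years
    yi <- match(sy, years)
    recs <- vector("list", length(sy))
    for (k in seq_along(sy)) {
      lam <- n_latent[, yi[k]]
      rows_sp <- integer(0); rows_tr <- integer(0); rows_bl <- integer(0)
      rows_sz <- numeric(0); rows_ab <- integer(0)
      for (i in seq_len(s_rich)) {
        pb <- if (quantize) {
          p <- numeric(length(mids))
          p[which.max(bin_probs[[present[i]]])] <- 1
          p
        } else {
          bin_probs[[present[i]]]
        }
        use <- which(pb > 0)
        n_cells <- n_tr * 2L * length(use)
        counts <- if (quantize) {
          rep(lam[i] * pb[use], times = n_tr * 2L)
        } else {
          stats::rpois(n_cells, rep(lam[i] * pb[use], times = n_tr * 2L))
        }
        pos <- counts > 0
        if (any(pos)) {
          grid_tr <- rep(seq_len(n_tr), each = 2L * length(use))
          grid_bl <- rep(rep(1:2, each = length(use)), times = n_tr)
          grid_sz <- rep(mids[use], times = n_tr * 2L)
          rows_sp <- c(rows_sp, rep(i, sum(pos)))
          rows_tr <- c(rows_tr, grid_tr[pos])
          rows_bl <- c(rows_bl, grid_bl[pos])
          rows_sz <- c(rows_sz, grid_sz[pos])
          rows_ab <- c(rows_ab, counts[pos])
        }
      }
      if (length(rows_sp)) {
        recs[[k]] <- data.frame(
          site_id = site$site_id,
          year = sy[k],
          transect_id = rows_tr,
          block_id = rows_bl,
          species_id = traits$species_id[present[rows_sp]],
          size_class = rows_sz,
          abundance = rows_ab,
          stringsAsFactors = FALSE
        )
      }
    }
    surveys_by_site[[s]] <- do.call(rbind, recs)
  }
  surveys <- do.call(rbind, c(surveys_by_site, list(make.row.names = FALSE)))
  ledger <- truth_ledger(cfg)
  if (cfg$effect_gravity_cv == 0 && cfg$effect_warming_cv == 0 &&
      cfg$richness_sst == 0 && cfg$trophic_optimum_cor == 0) {
    ledger <- ledger[0, , drop = FALSE]
    class(ledger) <- c("truth_ledger", "data.frame")
  }
  list(surveys = surveys, truth = ledger, latent = latent, config = cfg)
}
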