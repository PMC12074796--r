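#' Ground-truth standardized coefficients for the analysis structure
#'
#' A coefficient table on the stability path structure, with signs matching
#' the generator's qualitative rules (human pressure destabilizes species
#' and erodes trait diversity; warming trends destabilize species but raise
#' mean trophic level; warm seas are richer in trait diversity and
#' redundancy but lower in mean trophic level) and magnitudes in the
#' recoverable 0.2-0.5 band. Used with [simulate_path_data()] for
#' parameter-recovery and type-I-error experiments.
#'
#' @param scale Multiplier applied to every coefficient; `scale = 0` gives
#'   the null structure (no effects anywhere).
#' @return Data frame with `from`, `to`, `coef`.
#' @export
default_path_truth <- function(scale = 1) {
  tab <- data.frame(
    from = c("mean_sst", "sst_change", "cv_sst",
             "gravity", "mean_sst", "cv_chl",
             "mean_sst",
             "sst_change", "site_depth",
             "gravity", "sst_change", "mean_sst", "n_years",
             "cwm_trophic",
             "cwm_trophic", "fd1", "fr1", "cwm_depth"),
    to = c("cwm_trophic", "cwm_trophic", "cwm_trophic",
           "fd1", "fd1", "fd1",
           "fr1",
           "cwm_depth", "cwm_depth",
           "species_stability", "species_stability", "species_stability",
           "species_stability",
           "species_stability",
           "asynchrony", "asynchrony", "asynchrony", "asynchrony"),
    coef = c(-0.35, 0.30, -0.25,
             -0.35, 0.30, 0.25,
             0.30,
             0.30, 0.35,
             -0.35, -0.30, -0.25, 0.20,
             0.30,
             0.30, 0.35, 0.25, -0.25),
    stringsAsFactors = FALSE
  )
  tab$coef <- tab$coef * scale
  tab
}

#' Simulate site-level data from a linear-Gaussian path structure
#'
#' Generates one row per site directly from a directed acyclic graph with
#' known standardized coefficients: exogenous variables are standard
#' normal, each endogenous variable is the coefficient-weighted sum of its
#' parents plus Gaussian noise scaled so its marginal variance is 1 (hence
#' the population standardized coefficients equal `truth$coef` exactly),
#' and community stability is the deterministic equal-weight sum of the two
#' components. The errors of the two stability components can be
#' correlated.
#'
#' @param truth Coefficient table (`from`, `to`, `coef`), e.g.
#'   [default_path_truth()].
#' @param n Number of sites.
#' @param seed Integer seed.
#' @param exogenous Variables with no parents to generate as N(0, 1); by
#'   default inferred from `truth` plus the standard driver set.
#' @param error_cor Correlation between the errors of `species_stability`
#'   and `asynchrony` (both must be endogenous for it to apply).
#' @param sink_name Name of the deterministic sink column added as the
#'   equal-weight sum of `species_stability` and `asynchrony` (set `NULL`
#'   to skip).
#' @return Data frame of site-level variables.
#' @export
simulate_path_data <- function(truth, n, seed = 1L,
                               exogenous = NULL, error_cor = 0.3,
                               sink_name = "community_stability") {
  set.seed(seed)
  endo <- unique(truth$to)
  if (is.null(exogenous)) {
    exogenous <- union(setdiff(unique(truth$from), endo),
                       c("mean_sst", "sst_change", "cv_sst", "cv_chl",
                         "gravity", "site_depth", "n_years"))
    exogenous <- setdiff(exogenous, endo)
  }
  vars <- c(exogenous, topo_sort_truth(truth, endo))
  dat <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  for (v in exogenous) dat[, v] <- stats::rnorm(n)

  # correlated errors for the two components, unit marginal sd
  comp <- c("species_stability", "asynchrony")
  eps <- list()
  if (all(comp %in% vars) && abs(error_cor) > 0) {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    eps[[comp[1L]]] <- z1
    eps[[comp[2L]]] <- error_cor * z1 + sqrt(1 - error_cor^2) * z2
  }
  for (v in setdiff(vars, exogenous)) {
    rows <- truth[truth$to == v, , drop = FALSE]
    lin <- as.vector(dat[, rows$from, drop = FALSE] %*% rows$coef)
    v_lin_pop <- pop_linear_var(rows, truth, exogenous)
    if (v_lin_pop >= 1) {
      stop("structural coefficients into '", v,
           "' imply explained variance >= 1; reduce them")
    }
    e <- if (!is.null(eps[[v]])) eps[[v]] else stats::rnorm(n)
    dat[, v] <- lin + sqrt(1 - v_lin_pop) * e
  }
  dat <- as.data.frame(dat)
  if (!is.null(sink_name) && all(comp %in% vars)) {
    dat[[sink_name]] <- 0.5 * dat[[comp[1L]]] + 0.5 * dat[[comp[2L]]]
  }
  dat
}

# population variance of the linear predictor, from the implied covariance
# of the parents (exogenous are iid standard normal)
pop_linear_var <- function(rows, truth, exogenous) {
  parents <- rows$from
  k <- length(parents)
  cv <- matrix(0, k, k, dimnames = list(parents, parents))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      cv[i, j] <- pop_cov(parents[i], parents[j], truth, exogenous)
    }
  }
  as.vector(t(rows$coef) %*% cv %*% rows$coef)
}

# recursive population covariance between two variables of the structure
pop_cov <- function(a, b, truth, exogenous) {
  if (a == b) return(1)
  if (a %in% exogenous && b %in% exogenous) return(0)
  if (!(b %in% exogenous)) {
    rows <- truth[truth$to == b, , drop = FALSE]
    return(sum(rows$coef *
                 vapply(rows$from, pop_cov, numeric(1), b = a,
                        truth = truth, exogenous = exogenous)))
  }
  pop_cov(b, a, truth, exogenous)
}

topo_sort_truth <- function(truth, endo) {
  remaining <- endo
  sorted <- character(0)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v) {
      pa <- truth$from[truth$to == v]
      !any(pa %in% remaining[remaining != v])
    }, logical(1))]
    if (!length(ready)) stop("cycle in truth coefficient table")
    sorted <- c(sorted, ready)
    remaining <- setdiff(remaining, ready)
  }
  sorted
}
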