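#' Temporal stability of total community biomass
#'
#' Community stability is the inverse coefficient of variation of annual
#' total biomass: the mean of the yearly community totals divided by their
#' standard deviation across years.
#'
#' @param mat Numeric matrix of biomass, species in rows and years in
#'   columns. Values must be non-negative.
#' @return A single number, `mean(totals) / sd(totals)`. If the totals are
#'   constant (zero variance) the community never fluctuates and `Inf` is
#'   returned (with a warning) rather than an error.
#' @seealso [average_species_stability()], [synchrony()],
#'   [decompose_stability()]
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(3, 1, 2))
#' community_stability(m) # totals (4, 3, 5): 4 / 1 = 4
#' @export
community_stability <- function(mat) {
  mat <- check_biomass_matrix(mat)
  totals <- colSums(mat)
  s <- stats::sd(totals)
  if (s == 0) {
    warning("annual community totals are constant; stability is infinite")
    return(Inf)
  }
  mean(totals) / s
}

#' Biomass-weighted average species stability
#'
#' The species-level component of community stability: the reciprocal of
#' the biomass-weighted mean of species-level coefficients of variation.
#' Weighting each species' CV (`sd_i / m_i`) by its share of mean community
#' biomass (`m_i / m_c`) collapses to `CV_sp = sum(sd_i) / m_c`, so the
#' returned value is `m_c / sum(sd_i)`. This form satisfies the exact
#' partition `log S_c = log(1/CV_sp) - 1/2 log(phi)` used by
#' [decompose_stability()].
#'
#' @param mat Species x year biomass matrix.
#' @param form `"weighted_cv"` (default) for the partition-consistent form
#'   above; `"printed"` for the biomass-weighted sum of species-level
#'   inverse CVs, `sum_i (m_i / m_c) * (m_i / sd_i)`, which some authors
#'   report but which does not satisfy the partition identity.
#' @return A single number. Species with zero temporal mean are dropped
#'   with a warning; under `form = "printed"` species with zero variance
#'   are also dropped (their inverse CV is infinite).
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(3, 1, 2))
#' average_species_stability(m) # sd_i = (1, 1), m_c = 4: 4 / 2 = 2
#' @export
average_species_stability <- function(mat, form = c("weighted_cv", "printed")) {
  form <- match.arg(form)
  mat <- check_biomass_matrix(mat)
  m_i <- rowMeans(mat)
  if (any(m_i == 0)) {
    warning("dropping ", sum(m_i == 0), " species with zero mean biomass")
    mat <- mat[m_i > 0, , drop = FALSE]
    m_i <- m_i[m_i > 0]
  }
  if (nrow(mat) == 0L) stop("no species with positive mean biomass")
  sd_i <- apply(mat, 1L, stats::sd)
  m_c <- mean(colSums(mat))
  if (form == "weighted_cv") {
    if (sum(sd_i) == 0) {
      warning("all species are constant; average species stability is infinite")
      return(Inf)
    }
    m_c / sum(sd_i)
  } else {
    keep <- sd_i > 0
    if (!all(keep)) {
      warning("dropping ", sum(!keep), " constant species under form = \"printed\"")
    }
    sum((m_i[keep] / m_c) * (m_i[keep] / sd_i[keep]))
  }
}

#' Community-wide synchrony of species biomass fluctuations
#'
#' The variance-ratio synchrony index: the variance of the yearly community
#' totals (the sum of all elements of the species variance-covariance
#' matrix) divided by the variance the community would have if every
#' species fluctuated in perfect synchrony, `(sum_i sd_i)^2`. Bounded in
#' \[0, 1\]; 1 means perfectly synchronous fluctuations. Asynchrony is
#' `1 - phi` and captures compensatory dynamics.
#'
#' @inheritParams community_stability
#' @return `phi` in \[0, 1\] (up to floating point). `NaN` with a warning
#'   if every species is constant, in which case synchrony is undefined.
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(3, 1, 2))
#' synchrony(m) # vars 1 and 1, covariance -0.5: 1 / 4
#' @export
synchrony <- function(mat) {
  mat <- check_biomass_matrix(mat)
  v <- stats::cov(t(mat))
  denom <- sum(sqrt(diag(v)))^2
  if (denom == 0) {
    warning("all species are constant; synchrony is undefined")
    return(NaN)
  }
  sum(v) / denom
}

#' Partition community stability into species stability and asynchrony
#'
#' Computes community stability `S_c`, biomass-weighted average species
#' stability `1/CV_sp` and the synchrony index `phi` on one species x year
#' biomass matrix, together with the additive log-scale partition
#' `log S_c = log(1/CV_sp) - 1/2 log(phi)`, which holds exactly for the
#' variance-ratio synchrony index and the weighted-CV form of species
#' stability. The identity is asserted at `tol` before the object is
#' returned.
#'
#' @inheritParams community_stability
#' @param tol Absolute tolerance for the partition identity check.
#' @return An object of class `"stability_partition"`: a list with
#'   components `s_c`, `inv_cv_sp`, `phi`, `asynchrony` (`1 - phi`),
#'   `log_s_c`, `log_inv_cv_sp`, `log_asynchrony_term` (`-0.5 * log(phi)`),
#'   `m_c`, per-species means `m_i` and standard deviations `sd_i`, the
#'   variance-covariance matrix `v`, and `n_years`.
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(3, 1, 2))
#' decompose_stability(m)
#' @export
decompose_stability <- function(mat, tol = 1e-10) {
  mat <- check_biomass_matrix(mat)
  v <- stats::cov(t(mat))
  m_i <- rowMeans(mat)
  sd_i <- sqrt(diag(v))
  totals <- colSums(mat)
  m_c <- mean(totals)
  sd_c <- stats::sd(totals)
  if (sd_c == 0 || sum(sd_i) == 0) {
    stop("constant community biomass: the log partition is undefined; ",
         "use community_stability() for the infinite-stability signal")
  }
  s_c <- m_c / sd_c
  inv_cv_sp <- m_c / sum(sd_i)
  phi <- sum(v) / sum(sd_i)^2
  out <- structure(
    list(
      s_c = s_c,
      inv_cv_sp = inv_cv_sp,
      phi = phi,
      asynchrony = 1 - phi,
      log_s_c = log(s_c),
      log_inv_cv_sp = log(inv_cv_sp),
      log_asynchrony_term = -0.5 * log(phi),
      m_c = m_c,
      m_i = m_i,
      sd_i = sd_i,
      v = v,
      n_years = ncol(mat)
    ),
    class = "stability_partition"
  )
  gap <- abs(out$log_s_c - (out$log_inv_cv_sp + out$log_asynchrony_term))
  if (!is.finite(gap) || gap > tol) {
    stop("internal error: stability partition identity violated (gap = ",
         format(gap), ")")
  }
  out
}

#' @export
print.stability_partition <- function(x, digits = 4, ...) {
  cat("Community biomass stability partition (", x$n_years, " years, ",
      length(x$m_i), " species)\n", sep = "")
  cat(sprintf("  community stability   S_c      = %.*g\n", digits, x$s_c))
  cat(sprintf("  avg species stability 1/CV_sp  = %.*g\n", digits, x$inv_cv_sp))
  cat(sprintf("  synchrony             phi      = %.*g\n", digits, x$phi))
  cat(sprintf("  asynchrony            1 - phi  = %.*g\n", digits, x$asynchrony))
  cat(sprintf("  log S_c = log(1/CV_sp) - 0.5 log(phi): %.*g = %.*g + %.*g\n",
              digits, x$log_s_c, digits, x$log_inv_cv_sp,
              digits, x$log_asynchrony_term))
  invisible(x)
}

# shared validation for species x year inputs
check_biomass_matrix <- function(mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("'mat' must be a numeric species x year matrix")
  }
  if (ncol(mat) < 2L) stop("need at least 2 years of biomass")
  if (anyNA(mat)) stop("biomass matrix contains missing values")
  if (any(mat < 0)) stop("biomass must be non-negative")
  mat
}
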