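#' Community-weighted mean trait values
#'
#' Mean trait values weighted by species' relative biomass, computed on the
#' raw (untransformed) trait scales. Weights are typically the average
#' relative biomass of each species over the full time window.
#'
#' @param traits Data frame with one row per species; see
#'   [generate_species_pool()] for the expected columns. Any numeric
#'   columns may be supplied via `trait_cols`.
#' @param weights Numeric vector of relative biomass, one per row of
#'   `traits`, summing to 1.
#' @param trait_cols Character vector of trait columns to average.
#' @return Named numeric vector of community-weighted means.
#' @examples
#' tr <- data.frame(max_length = c(2, 4))
#' cwm(tr, c(0.25, 0.75), "max_length") # 3.5
#' @export
cwm <- function(traits, weights,
                trait_cols = c("trophic_level", "max_length",
                               "growth_coeff", "max_depth")) {
  if (length(weights) != nrow(traits)) {
    stop("length(weights) must equal nrow(traits)")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  missing_cols <- setdiff(trait_cols, names(traits))
  if (length(missing_cols)) {
    stop("missing trait columns: ", paste(missing_cols, collapse = ", "))
  }
  vapply(trait_cols, function(tc) sum(weights * traits[[tc]]), numeric(1))
}

#' Functional distances between species
#'
#' Euclidean distances in a standardized trait space. Maximum length and
#' maximum depth are log-transformed (they span orders of magnitude); all
#' traits are then z-scored over the supplied species pool so that no
#' trait dominates the distance by its unit of measurement. The threshold
#' `tau` is set to the mean off-diagonal distance, the level at which two
#' species are treated as fully distinct by [hill_functional()].
#'
#' @param traits Data frame of species traits (one row per species, with a
#'   `species_id` column used for labels when present).
#' @param trait_cols Traits entering the distance. The default uses all
#'   four; `c("max_length", "trophic_level", "max_depth")` restricts to the
#'   three traits conventional for distinctiveness.
#' @param log_cols Traits log-transformed before scaling; must be strictly
#'   positive.
#' @param standardize Z-score each (possibly logged) trait over the pool.
#'   Disable only if traits are already on a common scale.
#' @return Object of class `"trait_dist"`: list with the symmetric distance
#'   `matrix` (zero diagonal, species labels), `tau` (mean off-diagonal
#'   distance) and the transformed trait matrix `space`.
#' @export
trait_distances <- function(traits,
                            trait_cols = c("max_length", "growth_coeff",
                                           "trophic_level", "max_depth"),
                            log_cols = c("max_length", "max_depth"),
                            standardize = TRUE) {
  if (nrow(traits) < 2L) stop("need at least 2 species")
  missing_cols <- setdiff(trait_cols, names(traits))
  if (length(missing_cols)) {
    stop("missing trait columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- as.matrix(traits[, trait_cols, drop = FALSE])
  if (anyNA(x)) stop("traits contain missing values")
  for (lc in intersect(log_cols, trait_cols)) {
    if (any(x[, lc] <= 0)) {
      stop("trait '", lc, "' must be strictly positive for log transform")
    }
    x[, lc] <- log(x[, lc])
  }
  if (standardize) {
    x <- scale(x)
    # a trait constant over the pool carries no information; drop its axis
    x[, attr(x, "scaled:scale") == 0] <- 0
  }
  rownames(x) <- if ("species_id" %in% names(traits)) {
    as.character(traits$species_id)
  } else {
    rownames(traits)
  }
  d <- as.matrix(stats::dist(x))
  tau <- mean(d[upper.tri(d)])
  if (!is.finite(tau) || tau <= 0) {
    stop("tau (mean pairwise distance) must be positive; ",
         "are all species functionally identical?")
  }
  structure(list(matrix = d, tau = tau, space = x), class = "trait_dist")
}

#' @export
print.trait_dist <- function(x, ...) {
  cat("Functional distance matrix:", nrow(x$matrix), "species,",
      ncol(x$space), "trait axes; tau =", format(x$tau, digits = 4), "\n")
  invisible(x)
}

#' Taxonomic diversity as a Hill number of order one
#'
#' The effective number of equally abundant species: the exponential of
#' the Shannon entropy of the relative biomass weights. Zero weights are
#' dropped (the limit `p log p -> 0`).
#'
#' @param weights Non-negative relative biomass weights summing to 1.
#' @param q Hill order; only `q = 1` is used by the pipeline but other
#'   non-negative orders are accepted.
#' @return Effective species number in `[1, S]`.
#' @examples
#' hill_taxonomic(rep(0.25, 4)) # 4
#' @export
hill_taxonomic <- function(weights, q = 1) {
  p <- check_weights(weights)
  if (q == 1) {
    exp(-sum(p * log(p)))
  } else {
    sum(p^q)^(1 / (1 - q))
  }
}

#' Trait diversity as a functional Hill number of order one
#'
#' The effective number of equally distinct species under the
#' distance-threshold framework. Pairwise distances are truncated at
#' `tau` and rescaled, so species at distance `>= tau` are fully distinct
#' while species at distance 0 are indistinct:
#' `FD1 = exp(-sum_i p_i log(sum_j (1 - min(d_ij, tau)/tau) p_j))`.
#'
#' @param weights Relative biomass weights summing to 1 (zeros dropped
#'   together with their rows/columns of the distance matrix).
#' @param distances A `"trait_dist"` object, or a plain symmetric distance
#'   matrix (then `tau` must be given).
#' @param tau Distinctness threshold; defaults to the `tau` carried by a
#'   `"trait_dist"` object.
#' @param q Hill order (the pipeline uses 1).
#' @return `FD1` in `[1, TD1]`.
#' @export
hill_functional <- function(weights, distances, tau = NULL, q = 1) {
  if (inherits(distances, "trait_dist")) {
    if (is.null(tau)) tau <- distances$tau
    d <- distances$matrix
  } else {
    d <- as.matrix(distances)
  }
  if (is.null(tau) || !is.finite(tau) || tau <= 0) {
    stop("'tau' must be a positive number")
  }
  if (nrow(d) != length(weights)) {
    stop("distance matrix and weights differ in size")
  }
  keep <- weights > 0
  p <- check_weights(weights)
  d <- d[keep, keep, drop = FALSE]
  f <- 1 - pmin(d, tau) / tau   # similarity: 1 on the diagonal, 0 beyond tau
  a <- as.vector(f %*% p)       # effective abundance of species i's kind
  if (q == 1) {
    exp(-sum(p * log(a)))
  } else {
    sum(p * a^(q - 1))^(1 / (1 - q))
  }
}

#' Trait redundancy of order one
#'
#' The proportional gap between taxonomic and functional effective numbers,
#' `FR1 = 1 - FD1 / TD1`: the share of equally abundant species that could
#' be removed without reducing effective trait diversity.
#'
#' @param td1 Taxonomic Hill number from [hill_taxonomic()].
#' @param fd1 Functional Hill number from [hill_functional()].
#' @return `FR1` in `[0, 1 - 1/TD1]`.
#' @export
trait_redundancy <- function(td1, fd1) {
  if (fd1 > td1 * (1 + 1e-12)) {
    stop("internal consistency error: FD1 (", format(fd1),
         ") exceeds TD1 (", format(td1), ")")
  }
  1 - fd1 / td1
}

#' Trait distinctiveness of each species
#'
#' How unusual a species' trait combination is relative to the other
#' species in scope: the mean functional distance from species `i` to every
#' other species. The mean (rather than the raw sum over `S - 1`
#' neighbours) removes the direct dependence on species richness; the raw
#' sum is available with `normalize = FALSE`.
#'
#' @param distances `"trait_dist"` object or symmetric distance matrix.
#' @param species Optional character/integer index restricting the scope to
#'   one community's species (local distinctiveness). Default: full pool
#'   (global distinctiveness).
#' @param normalize Divide by `S - 1` (default) or return the raw sum.
#' @return Named numeric vector `D_i` over the species in scope.
#' @export
distinctiveness <- function(distances, species = NULL, normalize = TRUE) {
  d <- if (inherits(distances, "trait_dist")) distances$matrix else as.matrix(distances)
  if (!is.null(species)) d <- d[species, species, drop = FALSE]
  s <- nrow(d)
  if (s < 2L) {
    warning("distinctiveness is undefined for a single species")
    return(stats::setNames(NaN, rownames(d)))
  }
  tot <- rowSums(d)  # diagonal is zero, so this is the sum over j != i
  if (normalize) tot / (s - 1) else tot
}

#' Richness-residualized count of functionally distinct species
#'
#' Flags the top `quantile` share of the species pool by global trait
#' distinctiveness, counts how many of those occur in each community, and
#' returns the residuals of the simple linear regression of that count on
#' community species richness — the count of distinct species over and
#' above what richness alone predicts. Ties at the quantile threshold are
#' all included, so the flagged set is order-independent.
#'
#' @param occurrences List (one element per site) of character vectors of
#'   species present, or a logical/numeric site x species occurrence matrix
#'   with species as column names.
#' @param global_d Named vector of global distinctiveness over the pool
#'   (from [distinctiveness()]).
#' @param quantile Share of the pool flagged as distinct (default 0.25).
#' @return Data frame with `site_id`, `richness`, `n_distinct` and
#'   `n_distinct_residual`.
#' @export
n_distinct_residual <- function(occurrences, global_d, quantile = 0.25) {
  if (is.matrix(occurrences)) {
    sp <- colnames(occurrences)
    occurrences <- apply(occurrences > 0, 1L, function(r) sp[r],
                         simplify = FALSE)
  }
  if (length(occurrences) < 3L) stop("need at least 3 sites for the regression")
  if (is.null(names(global_d))) stop("'global_d' must be named by species")
  cutoff <- stats::quantile(global_d, probs = 1 - quantile, names = FALSE)
  distinct_sp <- names(global_d)[global_d >= cutoff]
  richness <- vapply(occurrences, length, integer(1))
  n_distinct <- vapply(occurrences,
                       function(s) sum(s %in% distinct_sp), integer(1))
  if (stats::var(richness) == 0) {
    stop("species richness has zero variance across sites; ",
         "the richness regression is undefined")
  }
  fit <- stats::lm(n_distinct ~ richness)
  data.frame(
    site_id = if (!is.null(names(occurrences))) names(occurrences) else
      seq_along(occurrences),
    richness = richness,
    n_distinct = n_distinct,
    n_distinct_residual = unname(stats::residuals(fit)),
    row.names = NULL
  )
}

#' All functional-diversity facets for a set of communities
#'
#' Convenience wrapper computing, per site, the community-weighted trait
#' means, taxonomic diversity `TD1`, trait diversity `FD1`, trait
#' redundancy `FR1`, species richness and the richness-residualized count
#' of functionally distinct species. Weights are each species' mean
#' relative biomass over the (gap-filled) window.
#'
#' @param matrices Named list of `"community_matrix"` objects (see
#'   [build_community_matrices()]).
#' @param traits Species trait table covering every species that occurs.
#' @param quantile Distinct-species quantile for [n_distinct_residual()].
#' @param distance_cols Traits used for the functional distance.
#' @return Data frame, one row per site (a `FacetTable`).
#' @export
facet_table <- function(matrices, traits, quantile = 0.25,
                        distance_cols = c("max_length", "growth_coeff",
                                          "trophic_level", "max_depth")) {
  stopifnot(length(matrices) >= 1L)
  td <- trait_distances(traits, trait_cols = distance_cols)
  gd <- distinctiveness(td)
  sp_index <- stats::setNames(seq_len(nrow(traits)),
                              as.character(traits$species_id))
  rows <- lapply(matrices, function(cm) {
    b <- cm$biomass
    m_i <- rowMeans(b)
    p <- m_i / sum(m_i)
    idx <- sp_index[rownames(b)]
    if (anyNA(idx)) {
      stop("species missing from trait table: ",
           paste(rownames(b)[is.na(idx)], collapse = ", "))
    }
    cw <- cwm(traits[idx, , drop = FALSE], p)
    td1 <- hill_taxonomic(p)
    fd1 <- if (length(p) >= 2L) {
      hill_functional(p, td$matrix[idx, idx, drop = FALSE], tau = td$tau)
    } else {
      1
    }
    data.frame(
      site_id = cm$site_id,
      cwm_trophic = cw[["trophic_level"]],
      cwm_length = cw[["max_length"]],
      cwm_growth = cw[["growth_coeff"]],
      cwm_depth = cw[["max_depth"]],
      td1 = td1, fd1 = fd1, fr1 = trait_redundancy(td1, fd1),
      richness = length(p)
    )
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  occ <- lapply(matrices, function(cm) rownames(cm$biomass))
  names(occ) <- vapply(matrices, `[[`, "", "site_id")
  if (length(occ) >= 3L && stats::var(out$richness) > 0) {
    nd <- n_distinct_residual(occ, gd, quantile = quantile)
    out$n_distinct <- nd$n_distinct
    out$n_distinct_residual <- nd$n_distinct_residual
  } else {
    out$n_distinct <- NA_integer_
    out$n_distinct_residual <- NA_real_
  }
  out
}

check_weights <- function(weights) {
  if (any(weights < 0) || anyNA(weights)) {
    stop("weights must be non-negative and non-missing")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  w <- weights[weights > 0]
  if (!length(w)) stop("all weights are zero")
  w / sum(w)
}
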