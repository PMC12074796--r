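# Independent brute-force oracles and small fixture builders.
# These deliberately re-derive quantities by literal summation so the
# package implementations are checked against something they do not share
# code with.

# exponential Shannon entropy by literal summation
td1_literal <- function(p) {
  p <- p[p > 0]
  exp(-sum(p * log(p)))
}

# functional Hill number of order 1 by literal double summation
fd1_literal <- function(p, d, tau) {
  keep <- p > 0
  p <- p[keep]
  d <- d[keep, keep, drop = FALSE]
  acc <- 0
  for (i in seq_along(p)) {
    inner <- 0
    for (j in seq_along(p)) {
      dij <- min(d[i, j], tau)
      inner <- inner + (1 - dij / tau) * p[j]
    }
    acc <- acc + p[i] * log(inner)
  }
  exp(-acc)
}

# total effect of `from` on `to`: exhaustive enumeration of directed paths
enumerate_total_effect <- function(edges, from, to) {
  if (from == to) return(1)
  out <- edges[edges$from == from, , drop = FALSE]
  if (!nrow(out)) return(0)
  s <- 0
  for (k in seq_len(nrow(out))) {
    s <- s + out$coef[k] * enumerate_total_effect(edges, out$to[k], to)
  }
  s
}

# random positive species x year biomass matrix
random_biomass_matrix <- function(n_sp, n_yr) {
  matrix(stats::rlnorm(n_sp * n_yr, meanlog = 2, sdlog = 0.7),
         n_sp, n_yr, dimnames = list(paste0("sp", seq_len(n_sp)),
                                     seq_len(n_yr) + 2007L))
}

# random relative-biomass weights (normalized exponentials)
random_weights <- function(s) {
  w <- stats::rexp(s)
  w / sum(w)
}

# random Euclidean distance matrix from points in trait space
random_distance_matrix <- function(s, dims = 3) {
  x <- matrix(stats::rnorm(s * dims), s)
  as.matrix(stats::dist(x))
}

# random sparse DAG with standardized-scale coefficients, as an edge list
random_sparse_dag <- function(n_nodes, p_edge = 0.3) {
  nodes <- paste0("v", seq_len(n_nodes))
  edges <- NULL
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (stats::runif(1) < p_edge) {
        edges <- rbind(edges, data.frame(
          from = nodes[i], to = nodes[j],
          coef = round(stats::runif(1, -0.5, 0.5), 3)
        ))
      }
    }
  }
  if (is.null(edges)) {
    edges <- data.frame(from = nodes[1], to = nodes[2], coef = 0.3)
  }
  edges
}

# a path_fit-shaped object carrying arbitrary edge coefficients, for
# testing effect accumulation without fitting anything
fit_from_edges <- function(edges, sink = NULL) {
  endo <- unique(edges$to)
  responses <- lapply(stats::setNames(endo, endo), function(v) {
    unique(edges$from[edges$to == v])
  })
  if (!is.null(sink)) responses[[sink$response]] <- NULL
  spec <- path_spec(responses, sink = sink)
  coefs <- data.frame(response = edges$to, term = edges$from,
                      estimate = edges$coef, se = NA_real_, p = NA_real_)
  structure(list(coefficients = coefs, spec = spec), class = "path_fit")
}

# tiny hand-written survey table: 1 site, 2 species, 2 transects x 2 blocks
tiny_survey <- function() {
  expand_rows <- function(...) data.frame(..., stringsAsFactors = FALSE)
  rbind(
    expand_rows(site_id = "s1", year = 2010, transect_id = 1, block_id = 1,
                species_id = "spA", size_class = 10, abundance = 3),
    expand_rows(site_id = "s1", year = 2010, transect_id = 1, block_id = 2,
                species_id = "spA", size_class = 10, abundance = 2),
    expand_rows(site_id = "s1", year = 2010, transect_id = 2, block_id = 1,
                species_id = "spB", size_class = 20, abundance = 1)
  )
}

tiny_traits <- function() {
  data.frame(
    species_id = c("spA", "spB"),
    max_length = c(15, 40), growth_coeff = c(0.5, 0.2),
    trophic_level = c(2.5, 4.0), max_depth = c(12, 30),
    lw_a = c(0.01, 0.02), lw_b = c(3, 3),
    stringsAsFactors = FALSE
  )
}

# spec matching the default ground-truth coefficient table exactly
truth_spec <- function(truth = default_path_truth()) {
  responses <- lapply(split(truth$from, truth$to), as.character)
  path_spec(
    responses,
    sink = list(response = "community_stability",
                parents = c("species_stability", "asynchrony")),
    correlated_errors = list(c("species_stability", "asynchrony"))
  )
}
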