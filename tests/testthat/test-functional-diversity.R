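test_that("community-weighted means are weighted averages on raw scales", {
  tr <- data.frame(max_length = c(2, 4), trophic_level = c(3, 3.5),
                   growth_coeff = c(0.1, 0.3), max_depth = c(5, 15))
  out <- cwm(tr, c(0.25, 0.75))
  expect_equal(unname(out["max_length"]), 3.5)
  expect_equal(unname(out["trophic_level"]), 0.25 * 3 + 0.75 * 3.5)
  expect_equal(unname(cwm(tr, c(0.5, 0.5))["max_depth"]), 10)
  expect_equal(unname(cwm(tr[1, ], 1)["growth_coeff"]), 0.1)
  expect_error(cwm(tr, c(0.5, 0.2)), "sum to 1")
  expect_error(cwm(tr, c(1)), "length")
})

test_that("trait distances log-transform, standardize, and set tau", {
  tr <- tiny_traits()
  td <- trait_distances(tr)
  expect_true(isSymmetric(td$matrix))
  expect_equal(diag(td$matrix), c(spA = 0, spB = 0))
  expect_equal(td$tau, mean(td$matrix[upper.tri(td$matrix)]))
  # identical species sit at distance zero
  tr2 <- rbind(tr, tr[1, ])
  tr2$species_id <- c("spA", "spB", "spC")
  td2 <- trait_distances(tr2)
  expect_equal(td2$matrix["spA", "spC"], 0)
  # permuting rows permutes the matrix
  td_rev <- trait_distances(tr[2:1, ])
  expect_equal(td_rev$matrix["spA", "spB"], td$matrix["spA", "spB"])
  expect_error(trait_distances(transform(tr, max_depth = c(-1, 5))),
               "strictly positive")
})

test_that("three collinear species give the hand-computed tau", {
  # one informative axis with standardized positions (0, 1, 3):
  # distances (1, 3, 2), tau = 2
  tr <- data.frame(species_id = c("a", "b", "c"),
                   max_length = c(10, 10, 10), growth_coeff = c(1, 1, 1),
                   trophic_level = c(3, 3, 3), max_depth = exp(c(0, 1, 3)))
  td <- trait_distances(tr, standardize = FALSE)
  expect_equal(td$matrix["a", "b"], 1)
  expect_equal(td$matrix["a", "c"], 3)
  expect_equal(td$matrix["b", "c"], 2)
  expect_equal(td$tau, 2)
  d <- distinctiveness(td)
  expect_equal(unname(d), c(2, 1.5, 2.5))
  expect_equal(unname(distinctiveness(td, normalize = FALSE)), c(4, 3, 5))
})

test_that("Hill numbers match closed forms and boundary laws", {
  expect_equal(hill_taxonomic(rep(0.25, 4)), 4)
  expect_equal(hill_taxonomic(1), 1)
  expect_equal(hill_taxonomic(c(0.5, 0.25, 0.25)), exp(1.5 * log(2)))
  # zero weights are dropped
  expect_equal(hill_taxonomic(c(0.5, 0.5, 0)), 2)
  # FD1 = 1 when all species are functionally identical
  z <- matrix(0, 3, 3)
  expect_equal(hill_functional(rep(1 / 3, 3), z, tau = 1), 1)
  # FD1 = TD1 when all pairwise distances reach tau
  far <- matrix(5, 3, 3); diag(far) <- 0
  w <- c(0.5, 0.3, 0.2)
  expect_equal(hill_functional(w, far, tau = 2), hill_taxonomic(w))
  # the two-species d = tau/2 case: inner sums 0.75, FD1 = 4/3
  half <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(hill_functional(c(0.5, 0.5), half, tau = 2), 4 / 3)
  expect_error(hill_functional(w, far, tau = 0), "tau")
})

test_that("FD1/TD1 equal literal-summation oracles on random communities", {
  set.seed(21)
  for (r in 1:60) {
    s <- sample(2:15, 1)
    w <- random_weights(s)
    d <- random_distance_matrix(s)
    tau <- mean(d[upper.tri(d)])
    td1 <- hill_taxonomic(w)
    fd1 <- hill_functional(w, d, tau = tau)
    expect_equal(td1, td1_literal(w), tolerance = 1e-12)
    expect_equal(fd1, fd1_literal(w, d, tau), tolerance = 1e-12)
    expect_gte(fd1, 1 - 1e-12)
    expect_lte(fd1, td1 + 1e-12)
    expect_lte(td1, s)
    fr1 <- trait_redundancy(td1, fd1)
    expect_gte(fr1, 0 - 1e-12)
    expect_lt(fr1, 1)
  }
})

test_that("FD1 weakly decreases as distances shrink", {
  set.seed(5)
  w <- random_weights(6)
  d <- random_distance_matrix(6)
  tau <- mean(d[upper.tri(d)])
  vals <- sapply(c(1, 0.7, 0.4, 0.1), function(k) {
    hill_functional(w, k * d, tau = tau)
  })
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("trait redundancy follows FR1 = 1 - FD1/TD1", {
  expect_equal(trait_redundancy(3, 3), 0)
  expect_equal(trait_redundancy(2, 1), 0.5)
  expect_equal(trait_redundancy(4, 4 / 3), 2 / 3)
  expect_error(trait_redundancy(2, 2.5), "exceeds")
})

test_that("distinctiveness behaves under symmetry and duplication", {
  const <- matrix(3, 4, 4); diag(const) <- 0
  expect_equal(unname(distinctiveness(const)), rep(3, 4))
  set.seed(9)
  for (r in 1:20) {
    d <- random_distance_matrix(sample(3:8, 1))
    rownames(d) <- colnames(d) <- paste0("s", seq_len(nrow(d)))
    di <- distinctiveness(d)
    # duplicate species 1: its mean distance can only drop or stay equal
    s <- nrow(d)
    d2 <- rbind(cbind(d, d[, 1]), c(d[1, ], 0))
    di2 <- distinctiveness(d2)
    expect_lte(di2[1], di[1] + 1e-12)
  }
  expect_warning(d1 <- distinctiveness(matrix(0, 1, 1)), "single species")
  expect_true(is.nan(d1))
})

test_that("richness-residualized distinct counts match a least-squares fit", {
  gd <- stats::setNames(c(5, 4, 3, 2, 1, 0.5, 0.2, 0.1), paste0("s", 1:8))
  # top 25% of 8 species by distinctiveness: s1, s2
  occ <- list(site1 = paste0("s", 1:8), site2 = paste0("s", 1:4),
              site3 = paste0("s", c(1, 5, 6)), site4 = paste0("s", 3:8),
              site5 = paste0("s", 1:2))
  out <- n_distinct_residual(occ, gd)
  expect_equal(out$n_distinct, c(2L, 2L, 1L, 0L, 2L))
  fit <- stats::lm(out$n_distinct ~ out$richness)
  expect_equal(out$n_distinct_residual, unname(stats::residuals(fit)))
  # counts exactly proportional to richness: residuals all ~ 0
  occ2 <- list(a = paste0("s", 1:2), b = paste0("s", 1:4),
               c = paste0("s", 1:8))
  out2 <- n_distinct_residual(occ2, gd)
  expect_equal(out2$n_distinct_residual, rep(0, 3), tolerance = 1e-12)
  expect_error(n_distinct_residual(occ[1:2], gd), "3 sites")
  expect_error(n_distinct_residual(list(a = "s1", b = "s1", c = "s1"), gd),
               "zero variance")
})

test_that("TD1 agrees with an independent Shannon implementation", {
  skip_if_not_installed("vegan")
  set.seed(30)
  for (r in 1:10) {
    w <- random_weights(sample(3:20, 1))
    expect_equal(hill_taxonomic(w),
                 exp(vegan::diversity(w, index = "shannon")),
                 tolerance = 1e-12)
  }
})

test_that("facet_table assembles coherent per-site facets", {
  tr <- generate_species_pool(40, seed = 14)
  cfg <- sim_config(gap_prob = 0.2, base_richness = 15)
  sites <- generate_sites(6, seed = 15, config = cfg)
  sim <- simulate_surveys(tr, sites, cfg, seed = 16)
  pl <- reef_pipeline(sim$surveys, tr, sites)
  ft <- pl$facets
  expect_true(all(ft$fd1 >= 1 - 1e-9))
  expect_true(all(ft$fd1 <= ft$td1 + 1e-9))
  expect_true(all(ft$td1 <= ft$richness + 1e-9))
  expect_true(all(ft$fr1 >= -1e-9 & ft$fr1 < 1))
  expect_true(all(c("cwm_trophic", "cwm_length", "cwm_growth", "cwm_depth",
                    "n_distinct_residual") %in% names(ft)))
})

test_that("global and local distinctiveness are strongly rank-correlated", {
  set.seed(31)
  tr <- generate_species_pool(60, seed = 31)
  td <- trait_distances(tr)
  gd <- distinctiveness(td)
  cors <- sapply(1:10, function(r) {
    sub <- sample(tr$species_id, 30)
    ld <- distinctiveness(td, species = sub)
    stats::cor(gd[sub], ld, method = "spearman")
  })
  expect_gt(mean(cors), 0.7)
})
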