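test_that("path specs validate structure", {
  expect_error(path_spec(list(a = "b", b = "a")), "cycle")
  expect_error(
    path_spec(list(y = c("x", "m"), m = "x"),
              correlated_errors = list(c("x", "m"))),
    "coincides"
  )
  sp <- default_path_spec()
  expect_s3_class(sp, "path_spec")
  expect_equal(sp$sink$parents, c("species_stability", "asynchrony"))
  expect_output(print(sp), "endogenous responses")
})

test_that("AICc all-subsets selection finds the generating predictor", {
  sel <- lapply(1:20, function(r) {
    set.seed(r)
    d <- data.frame(x1 = stats::rnorm(200), x2 = stats::rnorm(200),
                    x3 = stats::rnorm(200))
    d$y <- 2 * d$x1 + stats::rnorm(200)
    select_covariates("y", c("x1", "x2", "x3"), d)
  })
  # the generating predictor is always picked up; spurious ones only enter
  # at the usual information-criterion false-inclusion rate
  expect_gte(mean(vapply(sel, function(s) "x1" %in% s, logical(1))), 0.95)
  expect_lt(mean(vapply(sel, function(s) "x2" %in% s, logical(1))), 0.5)
  expect_lt(mean(vapply(sel, function(s) "x3" %in% s, logical(1))), 0.5)
  # single truly linked candidate is always selected
  set.seed(1)
  d <- data.frame(x1 = stats::rnorm(100))
  d$y <- d$x1 + stats::rnorm(100, 0, 0.5)
  expect_equal(select_covariates("y", "x1", d), "x1")
  # a null response is mostly left intercept-only
  empty <- vapply(1:20, function(r) {
    set.seed(100 + r)
    d <- data.frame(x1 = stats::rnorm(150), x2 = stats::rnorm(150),
                    y = stats::rnorm(150))
    length(select_covariates("y", c("x1", "x2"), d)) == 0L
  }, logical(1))
  expect_gt(mean(empty), 0.5)
  # collinearity and sample-size guards
  d2 <- data.frame(x1 = 1:10, x2 = 2 * (1:10), y = stats::rnorm(10))
  expect_error(select_covariates("y", c("x1", "x2"), d2), "collinear")
  expect_error(select_covariates("y", paste0("x", 1:9),
                                 as.data.frame(matrix(rnorm(100), 10))),
               "more observations")
})

test_that("AICc in the fast solver matches lm-based AICc", {
  set.seed(5)
  d <- data.frame(x1 = stats::rnorm(60), x2 = stats::rnorm(60))
  d$y <- 0.5 * d$x1 + stats::rnorm(60)
  # reproduce the ranking by brute force with stats::AIC
  ref <- sapply(list(character(0), "x1", "x2", c("x1", "x2")), function(ps) {
    f <- if (length(ps)) stats::reformulate(ps, "y") else y ~ 1
    fit <- stats::lm(f, d)
    k <- length(stats::coef(fit)) + 1
    stats::AIC(fit) + 2 * k * (k + 1) / (60 - k - 1)
  })
  expect_equal(select_covariates("y", c("x1", "x2"), d),
               list(character(0), "x1", "x2", c("x1", "x2"))[[
                 which.min(ref)]])
})

test_that("standardized coefficients behave and are affine-invariant", {
  set.seed(2)
  d <- data.frame(x = stats::rnorm(80))
  d$y <- d$x           # exact relation
  d$z <- stats::rnorm(80)
  sp <- path_spec(list(y = "x"))
  fit <- fit_path_model(sp, d)
  expect_equal(unname(coef(fit)["x -> y"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$r2["y"]), 1, tolerance = 1e-10)
  # affine rescaling of variables leaves standardized coefficients as-is
  set.seed(3)
  d2 <- data.frame(x = stats::rnorm(100))
  d2$y <- 0.4 * d2$x + stats::rnorm(100, 0, 0.8)
  f1 <- fit_path_model(sp, d2)
  d3 <- transform(d2, x = 100 * x - 7, y = 0.01 * y + 3)
  f2 <- fit_path_model(sp, d3)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  # permuting rows changes nothing
  f3 <- fit_path_model(sp, d2[sample(nrow(d2)), ])
  expect_equal(coef(f1), coef(f3), tolerance = 1e-10)
})

test_that("piecewise fits recover known standardized coefficients", {
  truth <- default_path_truth()
  spec <- truth_spec(truth)
  key <- paste(truth$from, truth$to)
  reps <- 40
  cover <- sign_ok <- matrix(NA, reps, nrow(truth))
  for (r in seq_len(reps)) {
    d <- simulate_path_data(truth, 500, seed = r)
    fit <- fit_path_model(spec, d)
    cf <- fit$coefficients
    i <- match(key, paste(cf$term, cf$response))
    est <- cf$estimate[i]; se <- cf$se[i]
    cover[r, ] <- truth$coef >= est - 1.96 * se &
      truth$coef <= est + 1.96 * se
    sign_ok[r, ] <- sign(est) == sign(truth$coef)
  }
  expect_true(all(colMeans(sign_ok) == 1))
  expect_true(all(colMeans(cover) >= 0.85))
  # residual correlation of the declared pair is detected
  d <- simulate_path_data(truth, 2000, seed = 99, error_cor = 0.3)
  fit <- fit_path_model(truth_spec(truth), d)
  expect_gt(fit$residual_cor[["species_stability ~~ asynchrony"]], 0.15)
  # the deterministic sink has r2 = 1
  expect_equal(unname(fit$r2["community_stability"]), 1, tolerance = 1e-9)
})

test_that("missing variables raise an explicit error", {
  sp <- path_spec(list(y = "x"))
  expect_error(fit_path_model(sp, data.frame(y = 1:5)), "missing from data")
})

test_that("Fisher's C combines claim p-values with the chi-square law", {
  out <- fisher_c_combine(c(0.5, 0.5))
  expect_equal(out$statistic, -2 * (log(0.5) + log(0.5)))
  expect_equal(out$statistic, 2.7726, tolerance = 1e-4)
  expect_equal(out$df, 4L)
  expect_equal(out$p_value, 0.596, tolerance = 1e-3)
  expect_error(fisher_c_combine(c(0.5, 0)), "p > 0")
})

test_that("a saturated structure yields C = 0, df = 0, p = 1", {
  set.seed(8)
  d <- data.frame(x = stats::rnorm(50))
  d$y <- 0.5 * d$x + stats::rnorm(50)
  fit <- suppressMessages(fit_path_model(path_spec(list(y = "x")), d))
  expect_equal(fit$fisher_c$statistic, 0)
  expect_equal(fit$fisher_c$df, 0L)
  expect_equal(fit$fisher_c$p_value, 1)
})

test_that("Fisher's C p-values are near-uniform when no path is missing", {
  truth <- default_path_truth(0)
  spec <- truth_spec(truth)
  pv <- vapply(1:150, function(r) {
    d <- simulate_path_data(truth, 150, seed = 2000 + r)
    fit_path_model(spec, d)$fisher_c$p_value
  }, numeric(1))
  ks <- stats::ks.test(pv, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(pv < 0.05), 0.0)   # some rejections occur
  expect_lt(mean(pv < 0.05), 0.12)  # but near the nominal rate
})

test_that("a missing strong path inflates Fisher's C", {
  truth <- default_path_truth()
  spec_missing <- truth_spec(truth)
  # remove the gravity -> species_stability edge from the fitted structure
  spec_missing$responses$species_stability <-
    setdiff(spec_missing$responses$species_stability, "gravity")
  spec_missing <- path_spec(spec_missing$responses, spec_missing$sink,
                            spec_missing$correlated_errors)
  rej <- vapply(1:30, function(r) {
    d <- simulate_path_data(truth, 300, seed = 3000 + r)
    fit_path_model(spec_missing, d)$fisher_c$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)
})

test_that("effect accumulation matches hand-computable chains", {
  edges <- data.frame(from = c("x", "m"), to = c("m", "y"),
                      coef = c(0.5, 0.4))
  fit <- fit_from_edges(edges)
  eff <- accumulate_effects(fit, outcomes = c("m", "y"))
  y <- eff[eff$driver == "x" & eff$outcome == "y", ]
  expect_equal(y$direct, 0)
  expect_equal(y$indirect, 0.2)
  expect_equal(y$total, 0.2)
  # direct plus mediated: 0.3 + 0.5 * 0.4
  edges2 <- rbind(edges, data.frame(from = "x", to = "y", coef = 0.3))
  eff2 <- accumulate_effects(fit_from_edges(edges2), outcomes = "y")
  expect_equal(eff2$direct, 0.3)
  expect_equal(eff2$total, 0.5)
  expect_equal(eff2$indirect, 0.2)
})

test_that("effect accumulation equals brute-force path enumeration", {
  set.seed(17)
  for (r in 1:30) {
    edges <- random_sparse_dag(sample(4:8, 1))
    fit <- fit_from_edges(edges)
    nodes <- unique(c(edges$from, edges$to))
    endo <- unique(edges$to)
    eff <- accumulate_effects(fit, outcomes = endo)
    for (i in seq_len(nrow(eff))) {
      expect_equal(
        eff$total[i],
        enumerate_total_effect(edges, eff$driver[i], eff$outcome[i]),
        tolerance = 1e-12
      )
    }
  }
})

test_that("community-stability effects are the weighted component sum", {
  truth <- default_path_truth()
  d <- simulate_path_data(truth, 1000, seed = 5)
  fit <- fit_path_model(truth_spec(truth), d)
  eff <- accumulate_effects(fit)
  w <- fit$coefficients[fit$coefficients$response == "community_stability", ]
  w <- stats::setNames(w$estimate, w$term)
  for (drv in unique(eff$driver)) {
    tot_cs <- eff$total[eff$driver == drv &
                          eff$outcome == "community_stability"]
    tot_sp <- eff$total[eff$driver == drv &
                          eff$outcome == "species_stability"]
    tot_as <- eff$total[eff$driver == drv & eff$outcome == "asynchrony"]
    expect_equal(tot_cs,
                 w[["species_stability"]] * tot_sp +
                   w[["asynchrony"]] * tot_as,
                 tolerance = 1e-10)
  }
  # total = direct + indirect identically
  expect_equal(eff$total, eff$direct + eff$indirect, tolerance = 1e-12)
})

test_that("selection-based fitting prunes facets that mediate nothing", {
  truth <- default_path_truth()
  d <- simulate_path_data(truth, 800, seed = 12)
  # an extra facet unrelated to everything
  set.seed(13)
  d$cwm_growth <- stats::rnorm(800)
  d$n_distinct_residual <- stats::rnorm(800)
  d$cwm_length <- stats::rnorm(800)
  spec <- default_path_spec(facets = c("cwm_trophic", "cwm_length",
                                       "cwm_growth", "cwm_depth", "fd1",
                                       "fr1", "n_distinct_residual"))
  fit <- fit_path_model(spec, d, selection = TRUE)
  expect_false("cwm_growth" %in% names(fit$models))
  expect_true(all(c("species_stability", "asynchrony") %in%
                    names(fit$models)))
  # strong true paths survive selection
  cf <- fit$coefficients
  expect_true(any(cf$response == "species_stability" & cf$term == "gravity"))
  expect_true(any(cf$response == "asynchrony" & cf$term == "fd1"))
})

test_that("path_fit methods expose the fit", {
  truth <- default_path_truth()
  d <- simulate_path_data(truth, 300, seed = 20)
  fit <- fit_path_model(truth_spec(truth), d)
  expect_output(print(fit), "Fisher's C")
  expect_output(print(summary(fit)), "residual correlations")
  expect_true(length(coef(fit)) >= nrow(truth))
  res <- residuals(fit)
  expect_equal(nrow(res), 300L)
  pdf(NULL)
  eff <- plot(fit)
  dev.off()
  expect_true(all(c("driver", "outcome", "total") %in% names(eff)))
})
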