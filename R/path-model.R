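#' Declare a piecewise path-model structure
#'
#' A path model is declared as a set of endogenous responses with their
#' candidate predictor sets, a deterministic sink (community stability,
#' which is fully determined by its two components), and unordered pairs
#' whose errors are allowed to correlate (and are therefore excluded from
#' the d-separation basis set together with any `exclude_pairs`).
#'
#' @param responses Named list: each element is the character vector of
#'   candidate parents for that endogenous variable.
#' @param sink List with `response` and its two `parents` (the stability
#'   components).
#' @param correlated_errors List of length-2 character vectors (unordered
#'   pairs); must not coincide with a directed edge.
#' @param exclude_pairs Additional unordered pairs excluded from the basis
#'   set (e.g. diversity facets computed from the same data, whose mutual
#'   correlation is acknowledged rather than modelled).
#' @return Object of class `"path_spec"`.
#' @export
path_spec <- function(responses, sink = NULL, correlated_errors = list(),
                      exclude_pairs = list()) {
  stopifnot(is.list(responses), !is.null(names(responses)))
  vars <- unique(c(names(responses), unlist(responses),
                   unlist(sink), unlist(correlated_errors)))
  edges <- do.call(rbind, lapply(names(responses), function(r) {
    if (length(responses[[r]])) data.frame(from = responses[[r]], to = r)
  }))
  if (!is.null(edges) && has_cycle(edges, vars)) {
    stop("the declared path structure contains a cycle")
  }
  for (p in correlated_errors) {
    stopifnot(length(p) == 2L)
    if (!is.null(edges) &&
        any((edges$from == p[1] & edges$to == p[2]) |
            (edges$from == p[2] & edges$to == p[1]))) {
      stop("correlated-error pair (", p[1], ", ", p[2],
           ") coincides with a directed edge")
    }
  }
  if (!is.null(sink)) {
    stopifnot(length(sink$parents) == 2L, !is.null(sink$response))
  }
  structure(
    list(responses = responses, sink = sink,
         correlated_errors = correlated_errors,
         exclude_pairs = exclude_pairs,
         variables = vars),
    class = "path_spec"
  )
}

#' @export
print.path_spec <- function(x, ...) {
  cat("Path model specification:", length(x$responses),
      "endogenous responses over", length(x$variables), "variables\n")
  for (r in names(x$responses)) {
    cat("  ", r, " ~ ", paste(x$responses[[r]], collapse = " + "), "\n",
        sep = "")
  }
  if (!is.null(x$sink)) {
    cat("  [sink] ", x$sink$response, " ~ ",
        paste(x$sink$parents, collapse = " + "), "\n", sep = "")
  }
  if (length(x$correlated_errors)) {
    cat("  correlated errors:",
        paste(vapply(x$correlated_errors, paste, "", collapse = " ~~ "),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Default path structure for the stability analysis
#'
#' The hypothesized structure: every abiotic driver may affect every
#' functional-diversity facet; drivers and facets may affect the two
#' stability components; community stability is the deterministic sink of
#' its two components. The errors of the two components are allowed to
#' correlate, and facet-facet pairs are excluded from the basis set since
#' the facets are computed from the same community data and their mutual
#' correlations are acknowledged, not modelled.
#'
#' @param drivers Exogenous abiotic/human variables.
#' @param facets Endogenous functional-diversity facets.
#' @param components The two stability components.
#' @return A `"path_spec"`.
#' @export
default_path_spec <- function(drivers = c("mean_sst", "sst_change", "cv_sst",
                                          "cv_chl", "gravity", "site_depth",
                                          "n_years"),
                              facets = c("cwm_trophic", "cwm_length",
                                         "cwm_growth", "cwm_depth", "fd1",
                                         "fr1", "n_distinct_residual"),
                              components = c("species_stability",
                                             "asynchrony")) {
  responses <- c(
    stats::setNames(rep(list(drivers), length(facets)), facets),
    stats::setNames(rep(list(c(drivers, facets)), length(components)),
                    components)
  )
  facet_pairs <- if (length(facets) >= 2L) {
    utils::combn(facets, 2L, simplify = FALSE)
  } else {
    list()
  }
  path_spec(
    responses,
    sink = list(response = "community_stability", parents = components),
    correlated_errors = list(components),
    exclude_pairs = facet_pairs
  )
}

#' All-subsets covariate selection by AICc
#'
#' Fits every subset of the candidate predictors by ordinary least squares
#' and returns the predictor set of the model with the lowest
#' small-sample-corrected Akaike information criterion. With
#' `delta = 2`, instead returns the union of predictors appearing in any
#' model within 2 AICc of the best.
#'
#' @param response Response variable name.
#' @param candidates Candidate predictor names.
#' @param data Data frame containing all variables.
#' @param delta `0` (default) for the single best model; a positive value
#'   to take the union over models within `delta` AICc of the best.
#' @return Character vector of selected predictors (possibly empty:
#'   intercept-only).
#' @export
select_covariates <- function(response, candidates, data, delta = 0) {
  n <- nrow(data)
  if (n <= length(candidates) + 2L) {
    stop("need more observations than candidates + 2")
  }
  x <- cbind(`(Intercept)` = 1, as.matrix(data[, candidates, drop = FALSE]))
  if (qr(x)$rank < ncol(x)) {
    stop("candidate predictors are perfectly collinear")
  }
  y <- data[[response]]
  # every subset solved from precomputed cross-products:
  # RSS = y'y - b'X'y with b from the normal equations of the submatrix
  xtx <- crossprod(x)
  xty <- crossprod(x, y)
  yty <- sum(y^2)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)),
                                       length(candidates))))
  aicc <- apply(subsets, 1L, function(inc) {
    idx <- c(1L, which(inc) + 1L)
    b <- solve(xtx[idx, idx, drop = FALSE], xty[idx, , drop = FALSE])
    rss <- yty - sum(b * xty[idx, ])
    p <- length(idx)
    k <- p + 1L  # + residual variance
    # Gaussian AIC as stats::AIC computes it, plus the small-sample term
    n * (log(2 * pi * rss / n) + 1) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  })
  best <- min(aicc)
  if (delta <= 0) {
    candidates[subsets[which.min(aicc), ]]
  } else {
    keep <- aicc <= best + delta
    candidates[colSums(subsets[keep, , drop = FALSE]) > 0]
  }
}

#' Fit a piecewise path model
#'
#' Estimates the declared structure as a set of local ordinary
#' least-squares regressions on z-standardized variables, so every
#' coefficient is a standardized path coefficient. Optionally runs
#' [select_covariates()] first on each endogenous response, and drops
#' facets that were selected for neither stability component (they cannot
#' mediate anything). The deterministic sink is fitted as a regression of
#' community stability on its two components, whose standardized
#' coefficients are the weights used by [accumulate_effects()]. Residual
#' Pearson correlations are reported for every declared correlated-error
#' pair, and the d-separation test ([fishers_c()]) is run on the fitted
#' structure.
#'
#' @param spec A `"path_spec"`.
#' @param data Data frame with one row per site and every spec variable.
#' @param selection Run AICc covariate selection before fitting.
#' @param delta Passed to [select_covariates()].
#' @param drop_unlinked_facets When selecting, remove endogenous variables
#'   that are not a selected parent of any other response (mediators with
#'   nothing to mediate).
#' @return Object of class `"path_fit"`: list with `coefficients` (one row
#'   per path: `response`, `term`, `estimate`, `se`, `p`), `r2` per
#'   response, `residual_cor`, `fisher_c` (see [fishers_c()]), the pruned
#'   `spec`, fitted `models`, standardized `data` and `n`.
#' @export
fit_path_model <- function(spec, data, selection = FALSE, delta = 0,
                           drop_unlinked_facets = TRUE) {
  stopifnot(inherits(spec, "path_spec"))
  vars <- spec$variables
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("variables missing from data: ",
         paste(missing_vars, collapse = ", "))
  }
  if (anyNA(data[, vars])) stop("data must be complete for all spec variables")
  zd <- as.data.frame(scale(data[, vars]))

  responses <- spec$responses
  if (selection) {
    responses <- lapply(names(responses), function(r) {
      select_covariates(r, spec$responses[[r]], zd, delta = delta)
    })
    names(responses) <- names(spec$responses)
    if (drop_unlinked_facets) {
      keep_going <- TRUE
      while (keep_going) {
        used <- unique(unlist(responses))
        if (!is.null(spec$sink)) used <- union(used, spec$sink$parents)
        drop <- setdiff(names(responses), used)
        keep_going <- length(drop) > 0L
        responses <- responses[setdiff(names(responses), drop)]
      }
    }
    spec <- path_spec(responses, sink = spec$sink,
                      correlated_errors = spec$correlated_errors,
                      exclude_pairs = spec$exclude_pairs)
  }

  fit_one <- function(r, parents) {
    f <- if (length(parents)) {
      stats::reformulate(parents, response = r)
    } else {
      stats::as.formula(paste(r, "~ 1"))
    }
    stats::lm(f, data = zd)
  }
  models <- lapply(names(responses), function(r) fit_one(r, responses[[r]]))
  names(models) <- names(responses)
  if (!is.null(spec$sink)) {
    models[[spec$sink$response]] <- fit_one(spec$sink$response,
                                            spec$sink$parents)
  }

  coefs <- do.call(rbind, lapply(names(models), function(r) {
    # the sink regression is (near-)deterministic; its perfect fit is expected
    sm <- suppressWarnings(summary(models[[r]]))$coefficients
    terms <- setdiff(rownames(sm), "(Intercept)")
    if (!length(terms)) return(NULL)
    data.frame(response = r, term = terms,
               estimate = sm[terms, 1L], se = sm[terms, 2L],
               p = sm[terms, 4L], row.names = NULL)
  }))
  r2 <- vapply(models,
               function(m) suppressWarnings(summary(m))$r.squared,
               numeric(1))
  residual_cor <- lapply(spec$correlated_errors, function(pr) {
    if (!all(pr %in% names(models))) {
      # an exogenous member: correlate the other's residuals with it
      res <- lapply(pr, function(v) {
        if (v %in% names(models)) stats::residuals(models[[v]]) else zd[[v]]
      })
      stats::cor(res[[1L]], res[[2L]])
    } else {
      stats::cor(stats::residuals(models[[pr[1L]]]),
                 stats::residuals(models[[pr[2L]]]))
    }
  })
  names(residual_cor) <- vapply(spec$correlated_errors, paste, "",
                                collapse = " ~~ ")

  out <- structure(
    list(coefficients = coefs, r2 = r2, residual_cor = residual_cor,
         spec = spec, models = models, data = zd, n = nrow(zd),
         selection = selection),
    class = "path_fit"
  )
  out$fisher_c <- fishers_c(out)
  out
}

#' @export
print.path_fit <- function(x, ...) {
  cat("Piecewise path model:", length(x$models), "local models, n =",
      x$n, "sites\n")
  fc <- x$fisher_c
  cat(sprintf("Fisher's C = %.3f, df = %d, p = %.3f (%d independence claims)\n",
              fc$statistic, fc$df, fc$p_value, nrow(fc$claims)))
  invisible(x)
}

#' @export
summary.path_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.path_fit")
}

#' @export
print.summary.path_fit <- function(x, digits = 3, ...) {
  fit <- x$fit
  print(fit)
  for (r in names(fit$models)) {
    cat("\n", r, " (r2 = ", format(fit$r2[[r]], digits = digits), ")\n",
        sep = "")
    rows <- fit$coefficients[fit$coefficients$response == r, , drop = FALSE]
    if (nrow(rows)) {
      print(data.frame(term = rows$term,
                       estimate = round(rows$estimate, digits),
                       se = round(rows$se, digits),
                       p = signif(rows$p, digits), row.names = NULL))
    } else {
      cat("  (intercept only)\n")
    }
  }
  if (length(fit$residual_cor)) {
    cat("\nresidual correlations:\n")
    for (nm in names(fit$residual_cor)) {
      cat("  ", nm, ": ", format(fit$residual_cor[[nm]], digits = digits),
          "\n", sep = "")
    }
  }
  invisible(x)
}

#' @export
coef.path_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  paste(object$coefficients$term, "->",
                        object$coefficients$response))
}

#' @export
residuals.path_fit <- function(object, ...) {
  sapply(object$models, stats::residuals)
}

#' @export
plot.path_fit <- function(x, outcomes = NULL, ...) {
  eff <- accumulate_effects(x)
  if (!is.null(outcomes)) eff <- eff[eff$outcome %in% outcomes, ]
  drivers <- setdiff(x$spec$variables,
                     c(names(x$spec$responses), x$spec$sink$response))
  eff <- eff[eff$driver %in% drivers, ]
  tab <- stats::xtabs(total ~ driver + outcome, data = eff)
  graphics::barplot(t(tab), beside = TRUE, las = 2,
                    legend.text = colnames(tab),
                    ylab = "total standardized effect",
                    main = "Accumulated effects of abiotic drivers", ...)
  invisible(eff)
}

#' D-separation test of the fitted structure (Fisher's C)
#'
#' Derives the basis set of independence claims implied by the fitted
#' directed acyclic graph — every non-adjacent variable pair, conditioned
#' on the parents of both, excluding pairs of exogenous variables,
#' declared correlated-error pairs, explicitly excluded pairs, and the
#' deterministic sink — tests each claim by the p-value of the omitted
#' variable added to the corresponding regression, and combines them as
#' `C = -2 * sum(log p)`, chi-squared with `2k` degrees of freedom under
#' the hypothesis that no path is missing.
#'
#' @param fit A `"path_fit"`.
#' @return List with `statistic`, `df`, `p_value` and the `claims` data
#'   frame (pair, conditioning set, p). An empty basis set (saturated
#'   model) gives `C = 0`, `df = 0`, `p = 1` with a message.
#' @export
fishers_c <- function(fit) {
  stopifnot(inherits(fit, "path_fit"))
  spec <- fit$spec
  responses <- spec$responses
  endo <- names(responses)
  sinkv <- spec$sink$response
  vars <- setdiff(spec$variables, sinkv)
  parents <- lapply(stats::setNames(vars, vars), function(v) {
    if (v %in% endo) responses[[v]] else character(0)
  })
  adj <- function(a, b) (a %in% parents[[b]]) || (b %in% parents[[a]])
  banned <- c(spec$correlated_errors, spec$exclude_pairs)
  is_banned <- function(a, b) {
    any(vapply(banned, function(p) setequal(p, c(a, b)), logical(1)))
  }
  anc <- ancestors(parents)
  claims <- list()
  if (length(vars) >= 2L) {
    prs <- utils::combn(vars, 2L, simplify = FALSE)
    for (p in prs) {
      a <- p[1L]; b <- p[2L]
      both_exo <- !(a %in% endo) && !(b %in% endo)
      if (both_exo || adj(a, b) || is_banned(a, b)) next
      # response: the non-ancestor of the pair (topologically later)
      resp <- if (a %in% anc[[b]]) b
      else if (b %in% anc[[a]]) a
      else if (b %in% endo) b else a
      other <- setdiff(c(a, b), resp)
      cond <- setdiff(union(parents[[resp]], parents[[other]]),
                      c(resp, other))
      f <- stats::reformulate(c(cond, other), response = resp)
      sm <- summary(stats::lm(f, data = fit$data))$coefficients
      claims[[length(claims) + 1L]] <- data.frame(
        independent = other, dependent = resp,
        conditioning = paste(cond, collapse = ", "),
        p = sm[other, 4L], row.names = NULL
      )
    }
  }
  if (!length(claims)) {
    message("saturated model: the basis set is empty")
    return(list(statistic = 0, df = 0L, p_value = 1,
                claims = data.frame(independent = character(0),
                                    dependent = character(0),
                                    conditioning = character(0),
                                    p = numeric(0))))
  }
  claims <- do.call(rbind, claims)
  c(fisher_c_combine(claims$p), list(claims = claims))
}

#' Combine independence-claim p-values into Fisher's C
#'
#' `C = -2 * sum(log(p))`, chi-squared with `2 * length(p)` degrees of
#' freedom when every claim holds.
#'
#' @param p Vector of independence-claim p-values.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
fisher_c_combine <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  cstat <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(statistic = cstat, df = df,
       p_value = stats::pchisq(cstat, df, lower.tail = FALSE))
}

#' Accumulate direct, indirect and total effects along paths
#'
#' Multiplies standardized coefficients along every directed path and sums
#' over paths: for each driver and each outcome, the direct effect is the
#' coefficient of the direct edge (0 if absent), the indirect effect is
#' the sum over all other directed paths of the product of coefficients
#' along the path, and the total is their sum. Effects on community
#' stability are the weighted combination of the effects on the two
#' components, with weights equal to the sink's standardized coefficients.
#' Computed by the matrix geometric series `B + B^2 + ...` of the
#' standardized edge-coefficient matrix, which terminates because the
#' graph is acyclic.
#'
#' @param fit A `"path_fit"`.
#' @param outcomes Outcome variables to report (default: the two stability
#'   components and the sink).
#' @return Data frame (`EffectDecomposition`) with `driver`, `outcome`,
#'   `direct`, `indirect`, `total`.
#' @export
accumulate_effects <- function(fit, outcomes = NULL) {
  stopifnot(inherits(fit, "path_fit"))
  spec <- fit$spec
  vars <- spec$variables
  b <- matrix(0, length(vars), length(vars), dimnames = list(vars, vars))
  for (i in seq_len(nrow(fit$coefficients))) {
    row <- fit$coefficients[i, ]
    b[row$term, row$response] <- row$estimate
  }
  total <- total_from_edges(b)
  if (is.null(outcomes)) {
    outcomes <- c(names(spec$responses), spec$sink$response)
    outcomes <- intersect(outcomes,
                          c("species_stability", "asynchrony",
                            spec$sink$response))
    if (!length(outcomes)) outcomes <- names(spec$responses)
  }
  drivers <- setdiff(vars, c(names(spec$responses), spec$sink$response))
  out <- expand.grid(driver = drivers, outcome = outcomes,
                     stringsAsFactors = FALSE)
  out$direct <- b[cbind(out$driver, out$outcome)]
  out$total <- total[cbind(out$driver, out$outcome)]
  out$indirect <- out$total - out$direct
  out[, c("driver", "outcome", "direct", "indirect", "total")]
}

# sum over all directed paths of products of edge coefficients:
# B + B^2 + ... , finite for a DAG
total_from_edges <- function(b) {
  n <- nrow(b)
  total <- b
  power <- b
  for (k in seq_len(n)) {
    power <- power %*% b
    if (all(power == 0)) break
    total <- total + power
  }
  if (!all(power == 0)) stop("cycle detected in the path structure")
  total
}

# ancestor sets from a parent map (named list)
ancestors <- function(parents) {
  anc <- lapply(parents, function(p) p)
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (v in names(anc)) {
      new <- unique(c(anc[[v]], unlist(anc[anc[[v]]])))
      if (length(new) > length(anc[[v]])) {
        anc[[v]] <- new
        changed <- TRUE
      }
    }
  }
  anc
}

has_cycle <- function(edges, vars) {
  parents <- lapply(stats::setNames(vars, vars),
                    function(v) edges$from[edges$to == v])
  anc <- ancestors(parents)
  any(vapply(names(anc), function(v) v %in% anc[[v]], logical(1)))
}
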