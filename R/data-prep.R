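#' @title Survey tables and community matrices
#' @description
#' A survey table is a long-format data frame of visual-census records with
#' columns `site_id`, `year`, `transect_id`, `block_id` (1 or 2, the two
#' sides of a transect line), `species_id`, `size_class` (total-length bin
#' midpoint, cm) and `abundance` (individuals counted). A community matrix
#' is the per-site end product: a species x year matrix of
#' transect-averaged biomass (g) with a parallel provenance flag matrix.
#' @name survey-data
NULL

SURVEY_COLS <- c("site_id", "year", "transect_id", "block_id",
                 "species_id", "size_class", "abundance")

check_survey_table <- function(surveys) {
  missing_cols <- setdiff(SURVEY_COLS, names(surveys))
  if (length(missing_cols)) {
    stop("survey table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(surveys$abundance < 0)) stop("abundance must be non-negative")
  if (any(surveys$size_class <= 0)) stop("size_class midpoints must be positive")
  surveys
}

#' Sum counts over the two blocks of each transect
#'
#' Divers record each side of a transect line as a separate block; the
#' first aggregation step sums abundances over blocks within each
#' (site, year, transect, species, size class) combination.
#'
#' @param surveys Survey table (see [survey-data]).
#' @return Data frame with the block dimension removed and `abundance`
#'   summed; all other key columns preserved.
#' @export
aggregate_blocks <- function(surveys) {
  check_survey_table(surveys)
  full_key <- do.call(paste, c(surveys[SURVEY_COLS[1:6]], sep = "\x1f"))
  if (anyDuplicated(full_key)) {
    stop("malformed survey table: duplicated (site, year, transect, block, ",
         "species, size_class) records")
  }
  if (nrow(surveys) == 0L) {
    out <- surveys[, setdiff(SURVEY_COLS, "block_id")]
    return(out)
  }
  grp_cols <- c("site_id", "year", "transect_id", "species_id", "size_class")
  key <- do.call(paste, c(surveys[grp_cols], sep = "\x1f"))
  sums <- rowsum(surveys$abundance, key)         # sorted by key
  first <- !duplicated(key)
  rep_rows <- surveys[first, grp_cols, drop = FALSE]
  rep_rows <- rep_rows[match(rownames(sums), key[first]), , drop = FALSE]
  rep_rows$abundance <- as.vector(sums)
  rownames(rep_rows) <- NULL
  rep_rows
}

#' Convert size-structured counts to annual species biomass
#'
#' Applies the length-weight relationship `w = lw_a * L^lw_b` (L the
#' size-class midpoint in cm, w in g) to each record, sums within
#' transects over size classes, then averages across all transects
#' surveyed at the (site, year) — transects where a species was not seen
#' contribute zero, so the average is the per-transect expectation.
#'
#' @param aggregated Block-aggregated table from [aggregate_blocks()].
#' @param traits Trait table with `species_id`, `lw_a` and `lw_b`.
#' @return Data frame with `site_id`, `year`, `species_id`, `biomass` (g).
#' @examples
#' agg <- data.frame(site_id = "s", year = 2010, transect_id = 1,
#'                   species_id = "sp", size_class = 10, abundance = 1)
#' tr <- data.frame(species_id = "sp", lw_a = 0.01, lw_b = 3)
#' biomass_from_counts(agg, tr)$biomass # 0.01 * 10^3 = 10 g
#' @export
biomass_from_counts <- function(aggregated, traits) {
  need <- c("site_id", "year", "transect_id", "species_id",
            "size_class", "abundance")
  missing_cols <- setdiff(need, names(aggregated))
  if (length(missing_cols)) {
    stop("aggregated table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  idx <- match(as.character(aggregated$species_id),
               as.character(traits$species_id))
  if (anyNA(idx)) {
    bad <- unique(aggregated$species_id[is.na(idx)])
    stop("no length-weight coefficients for species: ",
         paste(bad, collapse = ", "))
  }
  w <- traits$lw_a[idx] * aggregated$size_class^traits$lw_b[idx] *
    aggregated$abundance
  sy <- paste(aggregated$site_id, aggregated$year, sep = "\x1f")
  # transects surveyed per (site, year): any record defines presence
  syt <- paste(sy, aggregated$transect_id, sep = "\x1f")
  n_tr <- rowsum(as.numeric(!duplicated(syt)), sy)
  key <- paste(sy, aggregated$species_id, sep = "\x1f")
  sums <- rowsum(w, key)
  first <- !duplicated(key)
  out <- data.frame(
    site_id = aggregated$site_id[first],
    year = aggregated$year[first],
    species_id = aggregated$species_id[first],
    stringsAsFactors = FALSE
  )
  ord <- match(rownames(sums), key[first])
  out <- out[ord, , drop = FALSE]
  sy_of_key <- sub("\x1f[^\x1f]*$", "", rownames(sums))
  out$biomass <- as.vector(sums) / n_tr[match(sy_of_key, rownames(n_tr)), 1L]
  rownames(out) <- NULL
  out
}

#' Construct a community matrix
#'
#' @param site_id Site identifier.
#' @param biomass Species x year numeric matrix (column names are years).
#' @param flags Character matrix of the same shape with entries in
#'   `observed`, `zero_imputed`, `interpolated`, `edge_extrapolated`.
#' @param surveyed_years Integer vector of years actually surveyed.
#' @param window Closed year range covered by the study.
#' @return Object of class `"community_matrix"`.
#' @export
community_matrix <- function(site_id, biomass, flags = NULL,
                             surveyed_years = as.integer(colnames(biomass)),
                             window = c(2008L, 2021L)) {
  biomass <- as.matrix(biomass)
  if (is.null(colnames(biomass))) {
    stop("biomass matrix must have years as column names")
  }
  if (is.null(flags)) {
    flags <- matrix("observed", nrow(biomass), ncol(biomass),
                    dimnames = dimnames(biomass))
  }
  stopifnot(identical(dim(flags), dim(biomass)), all(biomass >= 0))
  structure(
    list(site_id = site_id, biomass = biomass, flags = flags,
         surveyed_years = as.integer(surveyed_years),
         window = as.integer(window)),
    class = "community_matrix"
  )
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("Community matrix for site", x$site_id, "-", nrow(x$biomass),
      "species x", ncol(x$biomass), "years;",
      length(x$surveyed_years), "surveyed years\n")
  invisible(x)
}

#' Assemble per-site community matrices from annual species biomass
#'
#' Pivots the output of [biomass_from_counts()] to one species x year
#' matrix per site over that site's surveyed years. A species-year cell
#' with no record in a surveyed year is a zero record (present at the site,
#' below detection that year) and gets biomass 0.
#'
#' @param biomass_df Long table from [biomass_from_counts()].
#' @param window Study year window.
#' @return Named list of `"community_matrix"` objects.
#' @export
build_community_matrices <- function(biomass_df, window = c(2008L, 2021L)) {
  split_df <- split(biomass_df, biomass_df$site_id)
  out <- lapply(split_df, function(d) {
    years <- sort(unique(d$year))
    species <- sort(unique(as.character(d$species_id)))
    b <- matrix(0, length(species), length(years),
                dimnames = list(species, years))
    b[cbind(match(as.character(d$species_id), species),
            match(d$year, years))] <- d$biomass
    keep <- rowSums(b) > 0
    community_matrix(d$site_id[1L], b[keep, , drop = FALSE],
                     surveyed_years = years, window = window)
  })
  out
}

#' Replace zero records by half the detection limit
#'
#' A zero record for a species previously observed at a site usually means
#' the species was present but below survey detection. Each zero in a
#' species' surveyed-year biomass series is replaced by half the minimum
#' positive biomass of that species at that site across surveyed years,
#' and flagged `zero_imputed`. Positive cells are never altered.
#'
#' @param cm A `"community_matrix"` (surveyed years only or gap-filled; the
#'   rule is applied to surveyed-year columns).
#' @return The community matrix with zeros imputed.
#' @export
impute_zero_records <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  cols <- as.character(cm$surveyed_years)
  b <- cm$biomass[, cols, drop = FALSE]
  all_zero <- rowSums(b) == 0
  if (any(all_zero)) {
    stop("species never observed at site ", cm$site_id, ": ",
         paste(rownames(b)[all_zero], collapse = ", "),
         " (zero replacement requires at least one positive record)")
  }
  for (i in seq_len(nrow(b))) {
    z <- b[i, ] == 0
    if (any(z)) {
      fill <- min(b[i, !z]) / 2
      cm$biomass[i, cols][z] <- fill
      cm$flags[i, cols][z] <- "zero_imputed"
    }
  }
  cm
}

#' Fill unsurveyed years by linear interpolation
#'
#' Expands a community matrix to the full study window. Interior gaps
#' (years between two surveys) are filled by linear interpolation of each
#' species' biomass; years before the first or after the last survey are
#' held constant at the nearest surveyed value. Surveyed-year cells are
#' never altered.
#'
#' @param cm A `"community_matrix"`.
#' @param window Year range to cover (defaults to the matrix's window).
#' @return Community matrix spanning every year of the window, with
#'   `interpolated` / `edge_extrapolated` flags on the filled cells.
#' @export
interpolate_missing_years <- function(cm, window = cm$window) {
  stopifnot(inherits(cm, "community_matrix"))
  years <- seq.int(window[1L], window[2L])
  sy <- sort(intersect(cm$surveyed_years, years))
  if (length(sy) < 1L) stop("site ", cm$site_id, " has no surveyed years in window")
  old_cols <- as.character(sy)
  b <- matrix(0, nrow(cm$biomass), length(years),
              dimnames = list(rownames(cm$biomass), years))
  fl <- matrix(ifelse(years < min(sy) | years > max(sy),
                      "edge_extrapolated", "interpolated"),
               nrow(cm$biomass), length(years), byrow = TRUE,
               dimnames = dimnames(b))
  new_sy_cols <- as.character(sy)
  fl[, new_sy_cols] <- cm$flags[, old_cols, drop = FALSE]
  for (i in seq_len(nrow(b))) {
    y <- cm$biomass[i, old_cols]
    b[i, ] <- if (length(sy) == 1L) {
      rep(y, length(years))
    } else {
      stats::approx(sy, y, xout = years, method = "linear", rule = 2)$y
    }
  }
  community_matrix(cm$site_id, b, fl, surveyed_years = sy, window = window)
}

#' Keep sites monitored often enough
#'
#' Retains only sites with at least `min_years` surveyed years inside the
#' study window.
#'
#' @param matrices List of `"community_matrix"` objects.
#' @param min_years Minimum number of surveyed years (inclusive).
#' @param window Year range the count is taken over.
#' @return The retained sublist, with attributes `n_kept` and `n_dropped`.
#' @export
filter_sites <- function(matrices, min_years = 7L, window = c(2008L, 2021L)) {
  n_sy <- vapply(matrices, function(cm) {
    sum(cm$surveyed_years >= window[1L] & cm$surveyed_years <= window[2L])
  }, integer(1))
  keep <- n_sy >= min_years
  out <- matrices[keep]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Sensitivity of stability estimates to gap interpolation
#'
#' On sites surveyed in every year of the window, randomly removes `n_drop`
#' years per site, refills them by [interpolate_missing_years()], and
#' correlates the log community stability computed from the gap-filled
#' series with the value from the raw series, across sites. Repeated
#' `reps` times to average over which years are dropped.
#'
#' @param complete List of fully surveyed `"community_matrix"` objects
#'   (positive biomass everywhere; run [impute_zero_records()] first).
#' @param n_drop Number of years to drop per site (0 <= n_drop < window
#'   length; at least 2 years must remain so stability is defined).
#' @param reps Number of random replicates.
#' @param seed Integer seed.
#' @return List with `n_drop`, `reps`, per-replicate Pearson
#'   `correlations` of log stability, and their `mean_correlation`.
#' @export
degrade_and_correlate <- function(complete, n_drop, reps = 10L, seed = 1L) {
  stopifnot(length(complete) >= 3L)
  window <- complete[[1L]]$window
  n_years <- window[2L] - window[1L] + 1L
  if (n_drop < 0 || n_drop > n_years - 2L) {
    stop("'n_drop' must leave at least 2 surveyed years in the window")
  }
  fully <- vapply(complete, function(cm) {
    length(intersect(cm$surveyed_years, seq.int(window[1L], window[2L]))) ==
      n_years
  }, logical(1))
  if (!all(fully)) {
    stop("all input sites must be surveyed in every year of the window")
  }
  years <- seq.int(window[1L], window[2L])
  raw <- vapply(complete, function(cm) {
    log(community_stability(cm$biomass[, as.character(years), drop = FALSE]))
  }, numeric(1))
  set.seed(seed)
  cors <- vapply(seq_len(reps), function(r) {
    if (n_drop == 0L) return(1)
    degraded <- vapply(complete, function(cm) {
      drop_years <- sample(years, n_drop)
      kept <- setdiff(years, drop_years)
      sub <- community_matrix(
        cm$site_id,
        cm$biomass[, as.character(kept), drop = FALSE],
        cm$flags[, as.character(kept), drop = FALSE],
        surveyed_years = kept, window = window
      )
      filled <- interpolate_missing_years(sub)
      log(community_stability(filled$biomass))
    }, numeric(1))
    stats::cor(raw, degraded)
  }, numeric(1))
  list(n_drop = n_drop, reps = reps, correlations = cors,
       mean_correlation = mean(cors))
}

#' Write / read a community matrix as plain CSV
#'
#' Serializes the biomass matrix (rows = species, columns = years) and the
#' parallel flag matrix to `<base>_biomass.csv` and `<base>_flags.csv`.
#'
#' @param cm A `"community_matrix"`.
#' @param base Path prefix (without extension).
#' @return `write_community_matrix()` returns `base` invisibly;
#'   `read_community_matrix()` returns the `"community_matrix"`.
#' @export
write_community_matrix <- function(cm, base) {
  utils::write.csv(as.data.frame(cm$biomass),
                   paste0(base, "_biomass.csv"), row.names = TRUE)
  fl <- as.data.frame(cm$flags)
  fl$.surveyed <- paste(cm$surveyed_years, collapse = ";")[1L]
  utils::write.csv(fl, paste0(base, "_flags.csv"), row.names = TRUE)
  invisible(base)
}

#' @param site_id Site identifier to attach on read.
#' @param window Study window to attach on read.
#' @rdname write_community_matrix
#' @export
read_community_matrix <- function(base, site_id = basename(base),
                                  window = c(2008L, 2021L)) {
  b <- utils::read.csv(paste0(base, "_biomass.csv"), row.names = 1L,
                       check.names = FALSE)
  fl <- utils::read.csv(paste0(base, "_flags.csv"), row.names = 1L,
                        check.names = FALSE)
  sy <- as.integer(strsplit(fl$.surveyed[1L], ";")[[1L]])
  fl <- as.matrix(fl[, setdiff(names(fl), ".surveyed"), drop = FALSE])
  community_matrix(site_id, as.matrix(b), fl, surveyed_years = sy,
                   window = window)
}
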