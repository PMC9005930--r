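# Synthetic-data generator: autocorrelated landscapes, logistic virtual
# species, occurrence sampling with optional access bias, trait tables,
# and synthetic road masks for the bias diagnostic.

# Separable Gaussian smoothing of a matrix with edge renormalisation.
# `range_cells` is the kernel radius in cells (the autocorrelation range).
smooth_field <- function(m, range_cells) {
  if (range_cells <= 0) return(m)
  r <- max(1L, as.integer(ceiling(range_cells)))
  sigma <- range_cells / 2
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  smooth1 <- function(mat) {
    n <- nrow(mat)
    out <- matrix(0, n, ncol(mat))
    wsum <- matrix(0, n, ncol(mat))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      keep <- src >= 1L & src <= n
      out[keep, ] <- out[keep, ] + k[j] * mat[src[keep], , drop = FALSE]
      wsum[keep, ] <- wsum[keep, ] + k[j]
    }
    out / wsum
  }
  t(smooth1(t(smooth1(m))))
}

#' Generate a synthetic covariate landscape
#'
#' Builds spatially autocorrelated covariate layers by Gaussian-kernel
#' smoothing of white noise, standardised to zero mean and unit variance
#' over the grid.  Requested pairwise correlations are imposed afterwards
#' by linear mixing (orthogonalise, then recombine), which reproduces each
#' target correlation essentially exactly in-sample.
#'
#' @param nrows,ncols grid dimensions (>= 8 for realistic fields).
#' @param cell_km cell size in km.
#' @param n_covariates number of layers (1-14); ignored when `codes` given.
#' @param autocorrelation_range kernel radius in cells.
#' @param correlation_pairs list of `list(code_a, code_b, r)` targets; each
#'   code may appear in at most one pair.
#' @param seed integer seed; generation is deterministic under it.
#' @param codes covariate codes to use; defaults to the first
#'   `n_covariates` of [covariate_codes()].
#' @param mask optional logical validity mask.
#' @return a [covariate_stack()].
#' @export
make_landscape <- function(nrows, ncols, cell_km = 1, n_covariates = 8,
                           autocorrelation_range = 6, correlation_pairs = list(),
                           seed = 1, codes = NULL, mask = NULL) {
  if (is.null(codes)) {
    if (n_covariates < 1 || n_covariates > 14)
      stopf("n_covariates must be between 1 and 14")
    codes <- covariate_codes()[seq_len(n_covariates)]
  }
  if (anyDuplicated(codes)) stopf("duplicate covariate codes")
  unknown <- setdiff(codes, covariate_codes())
  if (length(unknown)) stopf("unknown covariate code(s): %s", paste(unknown, collapse = ", "))

  pair_codes <- unlist(lapply(correlation_pairs, function(p) c(p[[1]], p[[2]])))
  if (anyDuplicated(pair_codes))
    stopf("unachievable correlation structure: a code appears in more than one pair")
  for (p in correlation_pairs) {
    if (!all(c(p[[1]], p[[2]]) %in% codes)) stopf("correlation pair names unknown code")
    if (abs(p[[3]]) > 1) stopf("unachievable correlation (|r| > 1): not positive semi-definite")
  }

  set.seed(seed)
  layers <- list()
  for (code in codes) {
    f <- smooth_field(matrix(stats::rnorm(nrows * ncols), nrows, ncols),
                      autocorrelation_range)
    layers[[code]] <- (f - mean(f)) / stats::sd(f)
  }
  # impose target correlations by exact in-sample mixing
  for (p in correlation_pairs) {
    a <- as.vector(layers[[p[[1]]]]); b <- as.vector(layers[[p[[2]]]])
    resid <- b - stats::cor(a, b) * a          # a, b are z-scored
    resid <- resid / stats::sd(resid)
    mixed <- p[[3]] * a + sqrt(1 - p[[3]]^2) * resid
    mixed <- (mixed - mean(mixed)) / stats::sd(mixed)
    layers[[p[[2]]]] <- matrix(mixed, nrows, ncols)
  }
  covariate_stack(grid_spec(nrows, ncols, cell_km), layers, mask = mask)
}

#' Define a virtual species on a landscape
#'
#' The species' true occurrence probability is the inverse logit of a
#' linear predictor in the chosen covariates, evaluated at every valid
#' cell.  This provides exact ground truth for pipeline validation.
#'
#' @param stack a [covariate_stack()].
#' @param response_vars covariate codes the species responds to.
#' @param coefficients numeric coefficients (logit scale), one per code.
#' @param intercept logit-scale intercept.
#' @param species_id identifier.
#' @return an object of class `virtual_species` with element
#'   `true_probability` (matrix in \[0, 1\], `NA` on masked cells).
#' @export
make_virtual_species <- function(stack, response_vars, coefficients,
                                 intercept = 0, species_id = "vs1") {
  unknown <- setdiff(response_vars, names(stack$layers))
  if (length(unknown)) stopf("unknown covariate code(s): %s", paste(unknown, collapse = ", "))
  if (length(response_vars) != length(coefficients))
    stopf("response_vars and coefficients must have equal length")
  eta <- matrix(intercept, stack$grid$nrows, stack$grid$ncols)
  for (i in seq_along(response_vars))
    eta <- eta + coefficients[i] * stack$layers[[response_vars[i]]]
  prob <- invlogit(eta)
  prob[!stack$mask] <- NA_real_
  structure(list(species_id = species_id, response_vars = response_vars,
                 coefficients = coefficients, intercept = intercept,
                 true_probability = prob, grid = stack$grid),
            class = "virtual_species")
}

#' Sample occurrence records from a virtual species
#'
#' Cells are drawn with replacement with probability proportional to
#' `true_probability * exp(access_bias_strength * access)`, emulating
#' detection effort concentrated in accessible areas when the bias strength
#' is positive.  Each record gets coordinates jittered uniformly within its
#' cell and a positional uncertainty drawn from a truncated normal.
#'
#' @param vs a [make_virtual_species()] object.
#' @param n_target number of records (>= 1).
#' @param access_bias_strength bias strength (0 = unbiased sampling).
#' @param access_raster matrix of access scores; required when the bias
#'   strength is nonzero.
#' @param uncertainty_km mean and sd of the positional-uncertainty
#'   distribution, in km.
#' @param seed integer seed.
#' @return data frame with columns species_id, x, y, uncertainty_km, source.
#' @export
sample_occurrences <- function(vs, n_target, access_bias_strength = 0,
                               access_raster = NULL,
                               uncertainty_km = c(mean = 0.3, sd = 0.2),
                               seed = 1) {
  if (n_target < 1) stopf("n_target must be >= 1")
  if (access_bias_strength != 0 && is.null(access_raster))
    stopf("access_raster is required when access_bias_strength != 0")
  p <- as.vector(vs$true_probability)
  w <- p
  if (access_bias_strength != 0)
    w <- w * exp(access_bias_strength * as.vector(access_raster))
  ok <- which(is.finite(w) & w > 0)
  if (!length(ok)) stopf("no cells with positive sampling probability")
  set.seed(seed)
  cells <- sample(ok, n_target, replace = TRUE, prob = w[ok])
  xy <- cell_xy(vs$grid, cells)
  half <- vs$grid$cell_km / 2
  x <- xy[, 1] + stats::runif(n_target, -half, half)
  y <- xy[, 2] + stats::runif(n_target, -half, half)
  unc <- abs(stats::rnorm(n_target, uncertainty_km[[1]], uncertainty_km[[2]]))
  data.frame(species_id = vs$species_id, x = x, y = y,
             uncertainty_km = unc, source = "synthetic",
             stringsAsFactors = FALSE)
}

#' Generate a synthetic species trait table
#'
#' One row per species with ten restoration-relevant attributes: growth
#' form, lifespan, bloom months, pollinator count, larval/adult pollinator
#' host flags, tortoise forage/cover flags, known-colonizer flag, and
#' propagation method.  Values are drawn from small categorical sets; the
#' table is deterministic for a given id list and seed.
#'
#' @param species_ids non-empty character vector of unique ids.
#' @param seed integer seed.
#' @return data frame, one row per species.
#' @export
make_trait_table <- function(species_ids, seed = 1) {
  if (!length(species_ids)) stopf("species_ids must be non-empty")
  if (anyDuplicated(species_ids)) stopf("duplicate species ids")
  n <- length(species_ids)
  set.seed(seed)
  months <- month.abb
  bloom_start <- sample(1:10, n, replace = TRUE)
  bloom_len <- sample(1:3, n, replace = TRUE)
  data.frame(
    species_id = as.character(species_ids),
    growth_form = sample(c("shrub", "forb", "grass", "cactus", "tree"), n, replace = TRUE),
    lifespan = sample(c("annual", "perennial"), n, replace = TRUE),
    bloom_months = vapply(seq_len(n), function(i)
      paste(months[bloom_start[i]:(bloom_start[i] + bloom_len[i])], collapse = "-"), ""),
    pollinator_count = sample(0:40, n, replace = TRUE),
    larval_host = sample(c(TRUE, FALSE), n, replace = TRUE),
    adult_host = sample(c(TRUE, FALSE), n, replace = TRUE),
    tortoise_forage = sample(c(TRUE, FALSE), n, replace = TRUE),
    tortoise_cover = sample(c(TRUE, FALSE), n, replace = TRUE),
    known_colonizer = sample(c(TRUE, FALSE), n, replace = TRUE),
    propagation_method = sample(c("seed", "container", "cutting"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Synthetic road / development mask
#'
#' Draws straight road transects across the grid (cells on each line are
#' marked as developed features).  Used by the bias diagnostic and by the
#' access-biased occurrence sampler.
#'
#' @param grid a [grid_spec()].
#' @param n_roads number of transects.
#' @param seed integer seed.
#' @return logical matrix, `TRUE` on feature cells.
#' @export
make_roads_mask <- function(grid, n_roads = 3, seed = 1) {
  set.seed(seed)
  m <- matrix(FALSE, grid$nrows, grid$ncols)
  for (i in seq_len(n_roads)) {
    if (stats::runif(1) < 0.5) {   # roughly horizontal transect
      r0 <- sample(grid$nrows, 1); r1 <- sample(grid$nrows, 1)
      cols <- seq_len(grid$ncols)
      rows <- round(seq(r0, r1, length.out = grid$ncols))
    } else {                       # roughly vertical transect
      c0 <- sample(grid$ncols, 1); c1 <- sample(grid$ncols, 1)
      rows <- seq_len(grid$nrows)
      cols <- round(seq(c0, c1, length.out = grid$nrows))
    }
    m[cbind(rows, cols)] <- TRUE
  }
  m
}

#' Access score from a distance raster
#'
#' Standardises negative distance so that cells near features score high;
#' convenient input for [sample_occurrences()]'s bias term.
#' @param dist_km distance raster (matrix, km).
#' @return matrix of zero-mean, unit-variance access scores.
#' @export
access_from_distance <- function(dist_km) {
  a <- -dist_km
  (a - mean(a, na.rm = TRUE)) / stats::sd(a, na.rm = TRUE)
}

#' Load the packaged 49-species SDM performance fixture
#'
#' Returns the published per-species results table bundled with the
#' package: species name, growth-form group, perennial-forb flag, number of
#' occurrence records, ensemble AUC and TSS, and the 13 printed
#' relative-importance columns (NDVI amplitude/maximum share the column
#' `AMP_MAXN`).  The file's checksum is verified on load.
#'
#' @return data frame with 49 rows.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "sdm_performance_49species.csv",
                      package = "seedmenus", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  expected <- "5129fc3099bc61634bca7e4cfae15978"
  if (!identical(md5, expected))
    stopf("fixture checksum mismatch for %s (got %s)", basename(path), md5)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) != 49) stopf("fixture must have 49 rows, found %d", nrow(df))
  df
}

#' Importance-column codes of the packaged performance fixture
#' @export
fixture_importance_codes <- function() {
  c("AHM", "CMD", "WP", "SP", "Tmax", "Tmin", "Trange",
    "HLI", "Slope", "TPI", "Text", "AMP_MAXN", "SWS")
}
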