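# Ground-truth validation experiments: desk-scale pipeline runs on
# simulated data with known generating models.  These are the package's
# calibration harness; the methods vignette describes the problem sizes.

#' Parameter-recovery experiment
#'
#' Runs the reduced-scale pipeline on a 64 x 64 synthetic landscape with 8
#' covariates and a virtual species responding to two of them (summer
#' precipitation, coefficient +3; summer maximum temperature, -2.5; logit
#' intercept -2), then checks whether the pipeline (i) ranks the two
#' causal covariates top-2 in the relative-importance table and (ii)
#' predicts habitat that discriminates an independent draw of presence
#' cells from random background cells.  Pipeline scale: at most 4 terms
#' per model, a seeded cap of 30 specs per family, 10 cross-validation
#' runs, 5 candidates kept per family.  Held-out AUC is measured on an
#' independent Bernoulli realization of the species (realized presence
#' versus realized absence cells).
#'
#' @param seed master seed.
#' @param n_occurrences occurrence records drawn for fitting.
#' @param spec_cap specs evaluated per algorithm family.
#' @return list: `result` (the `sdm_result`), `auc` (held-out
#'   overall-ensemble AUC), `importance`, `top2`, `causal`,
#'   `causal_top2` (logical).
#' @export
recovery_experiment <- function(seed = 1, n_occurrences = 500, spec_cap = 30) {
  codes <- c("SP", "WP", "Tmax", "Tmin", "Trange", "AHM", "CMD", "Slope")
  stack <- make_landscape(64, 64, codes = codes, autocorrelation_range = 6,
                          seed = fanout_seed(seed, "rec-land"))
  causal <- c("SP", "Tmax")
  vs <- make_virtual_species(stack, causal, c(3, -2.5), intercept = -2,
                             species_id = "recovery")
  occ <- sample_occurrences(vs, n_occurrences, seed = fanout_seed(seed, "rec-occ"))
  cfg <- pipeline_config(max_terms = 4, spec_cap = spec_cap, n_runs = 10,
                         n_keep = 5, compute_curves = FALSE)
  res <- suppressWarnings(
    run_species_sdm(stack, occ, lifespan = "perennial", config = cfg,
                    seed = seed, species_id = "recovery"))
  # independent evaluation: a seeded Bernoulli realization of the species
  # at every valid cell; held-out AUC is the ensemble's discrimination of
  # realized presence cells from realized absence cells
  p <- vs$true_probability
  ok <- which(is.finite(p))
  set.seed(fanout_seed(seed, "rec-test"))
  y <- stats::rbinom(length(ok), 1, p[ok])
  test_pres <- sample(ok[y == 1], 300, replace = TRUE)
  test_abs <- sample(ok[y == 0], 300, replace = TRUE)
  a <- auc(res$overall[test_pres], res$overall[test_abs])
  top2 <- names(sort(res$importance, decreasing = TRUE))[1:2]
  list(result = res, auc = a, importance = res$importance, top2 = top2,
       causal = causal, causal_top2 = setequal(top2, causal))
}

#' Sampling-bias sensitivity experiment
#'
#' Builds one 64 x 64 landscape with a synthetic road network, simulates
#' four virtual species, samples occurrences once without access bias and
#' once with the given bias strength towards roads (same seeds), runs the
#' reduced pipeline on both occurrence sets, and regresses the aggregated
#' habitat probabilities on distance to roads.  Systematic sampling bias
#' should surface as a larger coefficient of determination in the biased
#' arm.
#'
#' @param seed master seed.
#' @param bias_strength access-bias strength of the biased arm.
#' @return list: `r2_unbiased`, `r2_biased`, per-arm diagnostics.
#' @export
bias_experiment <- function(seed = 1, bias_strength = 5) {
  codes <- c("SP", "WP", "Tmax", "Tmin", "Slope", "CMD")
  stack <- make_landscape(64, 64, codes = codes, autocorrelation_range = 4,
                          seed = fanout_seed(seed, "bias-land"))
  roads <- make_roads_mask(stack$grid, n_roads = 4,
                           seed = fanout_seed(seed, "bias-roads"))
  access <- access_from_distance(distance_to_features(roads, stack$grid$cell_km))
  cfg <- pipeline_config(max_terms = 2, spec_cap = 8, n_runs = 4, n_keep = 3,
                         compute_curves = FALSE,
                         control = list(n_trees = 500, gam_k = 8,
                                        regmult = 1, n_hinge = 10))
  species <- list(list(id = "b1", vars = c("SP", "Tmax"), beta = c(3, -2.5)),
                  list(id = "b2", vars = c("WP", "Slope"), beta = c(-2.5, 3)),
                  list(id = "b3", vars = c("Tmin", "CMD"), beta = c(2.5, -3)),
                  list(id = "b4", vars = c("Slope", "SP"), beta = c(2.5, 2.5)))
  run_arm <- function(strength) {
    results <- lapply(species, function(sp) {
      vs <- make_virtual_species(stack, sp$vars, sp$beta, intercept = -2,
                                 species_id = sp$id)
      occ <- sample_occurrences(vs, 300, access_bias_strength = strength,
                                access_raster = if (strength != 0) access,
                                seed = fanout_seed(seed, "bias-occ", sp$id))
      suppressWarnings(
        run_species_sdm(stack, occ, lifespan = "perennial", config = cfg,
                        seed = fanout_seed(seed, "bias-fit", sp$id),
                        species_id = sp$id))
    })
    bias_diagnostic(results, roads, stack$grid$cell_km)
  }
  unbiased <- run_arm(0)
  biased <- run_arm(bias_strength)
  list(r2_unbiased = unbiased$r2_prob, r2_biased = biased$r2_prob,
       unbiased = unbiased, biased = biased)
}
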