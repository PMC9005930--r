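# Shared fixtures, built lazily and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# stack from explicit matrices (toy grids)
toy_stack <- function(..., mask = NULL, cell_km = 1) {
  layers <- list(...)
  g <- grid_spec(nrow(layers[[1]]), ncol(layers[[1]]), cell_km = cell_km)
  covariate_stack(g, layers, mask = mask)
}

# moderate landscape + strong-signal virtual species shared by learner and
# evaluation tests
signal_fixture <- function() {
  fixture("signal", function() {
    stack <- make_landscape(48, 48, n_covariates = 4, autocorrelation_range = 5,
                            seed = 101)
    vs <- make_virtual_species(stack, c("SP", "Tmax"), c(3, -3), intercept = -3)
    occ <- sample_occurrences(vs, 500, seed = 102)
    cells <- rasterize_presences(occ, stack$grid)
    bg <- suppressWarnings(
      sample_pseudo_absences(stack, cells, "maxent_like", seed = 103))
    ab <- sample_pseudo_absences(stack, cells, "tree_ensemble", seed = 104)
    list(stack = stack, vs = vs, occ = occ, cells = cells, bg = bg,
         presence = stack_values(stack, cells), background = stack_values(stack, bg),
         absence = stack_values(stack, ab))
  })
}

# small full pipeline run shared by ensemble/pipeline/menu tests
pipeline_fixture <- function() {
  fixture("pipeline", function() {
    sig <- signal_fixture()
    cfg <- pipeline_config(max_terms = 2, spec_cap = 8, n_runs = 3, n_keep = 3,
                           min_presences = 10, compute_curves = TRUE,
                           top_k_curves = 3,
                           control = list(n_trees = 300, gam_k = 8,
                                          regmult = 1, n_hinge = 10))
    run_species_sdm(sig$stack, sig$occ, lifespan = "perennial",
                    config = cfg, seed = 7, species_id = "vs_test")
  })
}

# brute-force Pearson correlation (two-pass) used as oracle
brute_cor <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force AUC over all presence/absence pairs
brute_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# brute-force all-pairs distance transform
brute_distance <- function(mask, cell_km = 1) {
  feat <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    out[i, j] <- sqrt(min((feat[, 1] - i)^2 + (feat[, 2] - j)^2))
  }
  out * cell_km
}
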