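# Orchestration of the full per-species pipeline: QC -> model space ->
# cross-validated evaluation of every spec -> candidate selection ->
# TSS-weighted ensembles, SE layer, overall ensemble, importance, curves.

#' Pipeline run configuration
#'
#' Houses the pipeline constants: at most 6 terms per model, correlation
#' cutoff 0.7, 50 cross-validation runs with a 20% holdout, ~10 candidates
#' per algorithm family, 10 km thinning blocks with at most 3 presences
#' each, 10,000 pseudo-absences for the smooth additive and maxent-like
#' families (presence-matched for the tree ensemble), 1000 trees.  Every
#' element is overridable; `spec_cap` takes a seeded random subsample of
#' the model space for desk-scale runs.
#'
#' @param max_terms maximum terms per model.
#' @param r_cut correlation cutoff.
#' @param spec_cap cap on the number of enumerated specs per family.
#' @param n_runs cross-validation runs.
#' @param holdout holdout fraction.
#' @param n_keep candidates kept per family.
#' @param block_km,max_per_block spatial-thinning parameters.
#' @param n_absences named list of per-family pseudo-absence counts
#'   (`NULL` = family default).
#' @param families algorithm families to run.
#' @param se_mode `"se"` or `"sd"` for the uncertainty layer.
#' @param min_presences minimum rasterized presence cells required.
#' @param top_k_curves number of top predictors for response curves.
#' @param compute_curves whether to compute response curves.
#' @param control learner hyperparameters (see [fit_sdm()]).
#' @export
pipeline_config <- function(max_terms = 6, r_cut = 0.7, spec_cap = Inf,
                            n_runs = 50, holdout = 0.2, n_keep = 10,
                            block_km = 10, max_per_block = 3,
                            n_absences = list(smooth_additive = NULL,
                                              tree_ensemble = NULL,
                                              maxent_like = NULL),
                            families = c("smooth_additive", "tree_ensemble", "maxent_like"),
                            se_mode = "se", min_presences = 20,
                            top_k_curves = 9, compute_curves = TRUE,
                            control = list(n_trees = 1000, gam_k = 10,
                                           regmult = 1, n_hinge = 20)) {
  cfg <- list(max_terms = max_terms, r_cut = r_cut, spec_cap = spec_cap,
              n_runs = n_runs, holdout = holdout, n_keep = n_keep,
              block_km = block_km, max_per_block = max_per_block,
              n_absences = n_absences, families = families, se_mode = se_mode,
              min_presences = min_presences, top_k_curves = top_k_curves,
              compute_curves = compute_curves, control = control)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, field, why) if (!ok) stopf("invalid config field '%s': %s", field, why)
  chk(cfg$max_terms >= 1, "max_terms", "must be >= 1")
  chk(cfg$r_cut > 0 && cfg$r_cut <= 1, "r_cut", "must be in (0, 1]")
  chk(cfg$n_runs >= 1, "n_runs", "must be >= 1")
  chk(cfg$holdout > 0 && cfg$holdout < 1, "holdout", "must be in (0, 1)")
  chk(cfg$n_keep >= 1, "n_keep", "must be >= 1")
  chk(all(cfg$families %in% c("smooth_additive", "tree_ensemble", "maxent_like")),
      "families", "unknown algorithm family")
  chk(cfg$se_mode %in% c("se", "sd"), "se_mode", "must be 'se' or 'sd'")
  invisible(cfg)
}

raster_from_valid <- function(stack, values) {
  m <- matrix(NA_real_, stack$grid$nrows, stack$grid$ncols)
  m[valid_cells(stack)] <- values
  m
}

#' Run the full SDM pipeline for one species
#'
#' @param stack a [covariate_stack()].
#' @param occ occurrence data frame (columns x, y, optionally
#'   uncertainty_km).
#' @param lifespan `"annual"` or `"perennial"` (controls NDVI-covariate
#'   eligibility when both AMP and MAXN layers are present).
#' @param config a [pipeline_config()].
#' @param seed master seed; all per-run randomness is fanned out from it.
#' @param species_id identifier used in outputs and seed fan-out.
#' @param water_mask optional logical water mask for QC.
#' @return an object of class `sdm_result`: evaluated specs, candidate
#'   sets, per-family ensemble rasters, overall ensemble, SE layer,
#'   relative-importance row, response curves, species max-SSS threshold.
#' @export
run_species_sdm <- function(stack, occ, lifespan = "perennial",
                            config = pipeline_config(), seed = 1,
                            species_id = "species", water_mask = NULL) {
  validate_config(config)
  occ <- qc_filter(occ, stack, water_mask = water_mask)
  presence_cells <- rasterize_presences(occ, stack$grid)
  if (length(presence_cells) < config$min_presences)
    stopf("species '%s': only %d presence cells (< %d)", species_id,
          length(presence_cells), config$min_presences)

  codes <- names(stack$layers)
  corr <- correlation_matrix(stack)
  specs <- enumerate_models(codes, corr, config$max_terms, config$r_cut)
  if (all(c("AMP", "MAXN") %in% codes)) specs <- lifespan_filter(specs, lifespan)
  specs <- cap_specs(specs, config$spec_cap, seed = fanout_seed(seed, species_id, "cap"))

  evaluated <- list(); cand_sets <- list(); fam_rasters <- list()
  all_cand_rasters <- list(); fam_importances <- list(); fam_fits <- list()
  fam_weights <- list()

  for (fam in config$families) {
    ev <- lapply(names(specs), function(sid) {
      cv <- cross_validate(specs[[sid]], fam, stack, presence_cells,
                           n_runs = config$n_runs, holdout = config$holdout,
                           seed = fanout_seed(seed, species_id, fam, sid),
                           config = config)
      data.frame(spec_id = sid, variables = paste(specs[[sid]], collapse = "+"),
                 auc = cv$mean[["auc"]], tss = cv$mean[["tss"]],
                 boyce = cv$mean[["boyce"]], aicc = cv$mean[["aicc"]],
                 threshold = cv$mean[["threshold"]],
                 stringsAsFactors = FALSE)
    })
    ev <- do.call(rbind, ev)
    evaluated[[fam]] <- ev
    sel <- select_candidates(ev, config$n_keep)
    cand_sets[[fam]] <- sel

    # refit the selected candidates (same seeds reproduce the CV runs) and
    # keep per-run predictions and importances
    rasters <- list(); imps <- list(); reps <- list()
    for (i in seq_len(nrow(sel$candidates))) {
      sid <- sel$candidates$spec_id[i]
      cv <- cross_validate(specs[[sid]], fam, stack, presence_cells,
                           n_runs = config$n_runs, holdout = config$holdout,
                           seed = fanout_seed(seed, species_id, fam, sid),
                           config = config, keep_fits = TRUE, keep_predictions = TRUE)
      rasters[[sid]] <- raster_from_valid(stack, rowMeans(cv$predictions))
      run_imps <- lapply(cv$fits, sdm_importance)
      imps[[sid]] <- Reduce(`+`, run_imps) / length(run_imps)
      reps[[sid]] <- cv$fits[[1]]
    }
    fam_rasters[[fam]] <- predict_family_ensemble(rasters, sel$weights)
    all_cand_rasters <- c(all_cand_rasters, rasters)
    fam_importances[[fam]] <- imps
    fam_fits[[fam]] <- reps
    fam_weights[[fam]] <- sel$weights
  }

  overall <- overall_ensemble(fam_rasters)
  se <- se_layer(all_cand_rasters, mode = config$se_mode)
  importance <- relative_importance(fam_importances, codes)

  curves <- NULL
  if (config$compute_curves) {
    top <- names(sort(importance, decreasing = TRUE))
    top <- utils::head(top, config$top_k_curves)
    top <- top[vapply(top, function(code) any(unlist(lapply(fam_fits, function(ff)
      vapply(ff, function(f) code %in% f$variables, TRUE)))), TRUE)]
    if (length(top))
      curves <- response_curves(fam_fits, fam_weights, top, stack)
  }

  # species-level max-SSS threshold on the overall ensemble
  bg <- sample_pseudo_absences(stack, presence_cells, "maxent_like",
                               seed = fanout_seed(seed, species_id, "thr"))
  lab <- c(rep(1L, length(presence_cells)), rep(0L, length(bg)))
  thr <- max_sss_threshold(lab, c(overall[presence_cells], overall[bg]))

  structure(list(species_id = species_id, lifespan = lifespan,
                 n_presence_cells = length(presence_cells),
                 qc_report = attr(occ, "qc_report"),
                 evaluated = evaluated, candidates = cand_sets,
                 family_rasters = fam_rasters, overall = overall, se = se,
                 importance = importance, curves = curves,
                 threshold_max_sss = thr$threshold, threshold_tss = thr$tss,
                 seed = seed, config = config),
            class = "sdm_result")
}

#' @export
print.sdm_result <- function(x, ...) {
  cat(sprintf("<sdm_result> %s: %d presence cells, %d families\n",
              x$species_id, x$n_presence_cells, length(x$family_rasters)))
  for (fam in names(x$candidates)) {
    c1 <- x$candidates[[fam]]$candidates[1, ]
    cat(sprintf("  %s: %d candidates, best TSS %.3f (AUC %.3f)\n", fam,
                nrow(x$candidates[[fam]]$candidates), c1$tss, c1$auc))
  }
  cat(sprintf("  max-SSS threshold %.3f; top predictors: %s\n", x$threshold_max_sss,
              paste(utils::head(names(sort(x$importance, decreasing = TRUE)), 3),
                    collapse = ", ")))
  invisible(x)
}

#' Export per-spec evaluation metrics as a data frame
#' @param result an `sdm_result`.
#' @export
metrics_table <- function(result) {
  do.call(rbind, lapply(names(result$evaluated), function(fam) {
    df <- result$evaluated[[fam]]
    cbind(species_id = result$species_id, family = fam, df,
          stringsAsFactors = FALSE)
  }))
}
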