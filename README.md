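# seedmenus

Ensemble species distribution models (SDMs) and a "seed menu" decision-support
engine for native-plant restoration planning in arid landscapes.

## The problem

Restoration practitioners designing seed mixes need to know *which native
species have suitable habitat at their project sites*, and which traits those
species bring (growth form, bloom period, pollinator services, tortoise
forage/cover, propagation method). `seedmenus` provides the full workflow:

1. **Ensemble SDMs per species.** Presence-only occurrence records are
   quality-controlled (positional uncertainty ≤ 1 km, water/masked cells
   dropped), rasterized to the 1-km modelling grid, and spatially thinned (at
   most 3 presence cells per 10 km × 10 km block). Three algorithm families
   are fit over all covariate subsets of at most six terms, excluding pairs
   with Pearson |r| > 0.7:

   * a penalized binomial additive model (one shrinkage smooth per covariate,
     REML; terms can be penalized to ~0 effective degrees of freedom),
   * a 1000-tree classification random forest,
   * a maximum-entropy presence/background model (linear, quadratic, product
     and hinge features under an L1 path; raw output normalized over the
     background).

   Each model spec is evaluated across cross-validation runs (default 50),
   each run drawing fresh thinned presences and fresh pseudo-absences
   (10,000 background points for the additive and maximum-entropy families,
   presence-matched absences for the forest) and withholding a stratified
   20 % for evaluation by AUC, the True Skill Statistic at the
   max(sensitivity + specificity) threshold, the continuous Boyce index and
   AICc. Roughly 10 well-performing candidates per family are combined by
   TSS-weighted averaging; the three family ensembles are averaged into the
   overall habitat-probability layer, with a standard-error layer across all
   candidates, a relative-importance row (permutation importance / mean
   decrease in accuracy / smooth-term edf, normalized to sum 100) and
   model-averaged response curves.

2. **Seed menus.** Per-species habitat layers are stacked; probabilities are
   extracted at restoration sites (points or single-ring polygons); a species
   enters the menu iff its probability is **≥ the threshold at every site**
   (fixed threshold or per-species max-SSS). Included species are joined to
   their trait records; a coverage map counts species with suitable habitat
   per cell.

3. **Bias diagnostic.** Aggregated habitat probabilities (and SE layers)
   across species are regressed on distance to roads/development with a
   penalized smooth; a large R² flags systematic accessibility bias in the
   occurrence data.

4. **Synthetic data with known truth.** `make_landscape()` (autocorrelated,
   optionally cross-correlated covariate fields), `make_virtual_species()`
   (logistic responses, exact ground truth), `sample_occurrences()` (optional
   access bias towards roads), `make_trait_table()`. A published 49-species
   performance table ships as a verified fixture
   (`load_table2_fixture()`).

## Worked example

```r
library(seedmenus)

# simulate a landscape and two virtual species with known responses
sim <- simulate_inputs(n_species = 2, nrows = 48, ncols = 48,
                       n_covariates = 6, n_occurrences = 400, seed = 42)

# desk-scale pipeline settings (full-scale defaults: 6 terms, 50 runs, 10 kept)
cfg <- pipeline_config(max_terms = 2, spec_cap = 10, n_runs = 5, n_keep = 3,
                       compute_curves = FALSE)

fits <- lapply(names(sim$occurrences), function(sid)
  run_species_sdm(sim$stack, sim$occurrences[[sid]], lifespan = "perennial",
                  config = cfg, seed = 42, species_id = sid))
names(fits) <- names(sim$occurrences)
fits$vs01
#> <sdm_result> vs01: 338 presence cells, 3 families
#>   smooth_additive: 3 candidates, best TSS 0.359 (AUC 0.656)
#>   tree_ensemble: 3 candidates, best TSS 0.293 (AUC 0.600)
#>   maxent_like: 3 candidates, best TSS 0.442 (AUC 0.705)
#>   max-SSS threshold 0.521; top predictors: AHM, Tmin, WP
```

The cross-validated AUC/TSS are per-run holdout means — conservative at this
desk scale, where thinning leaves few training presences. The importance
table still recovers the generating model: `vs01` was simulated to respond
to AHM and Tmin only, and those two codes take 89 of the 100 importance
points:

```r
sim$species$vs01$response_vars
#> [1] "AHM"  "Tmin"
round(sort(fits$vs01$importance, decreasing = TRUE), 1)
#>    AHM   Tmin     WP     SP   Tmax Trange
#>   53.8   34.9    4.0    3.8    1.8    1.6
```

A seed menu for two candidate restoration sites, with an inclusive 0.4
threshold applied at *all* sites (`vs02` fails at siteA and is excluded):

```r
sites <- site_set(coords = data.frame(site_id = c("siteA", "siteB"),
                                      x = c(12.5, 30.5), y = c(12.5, 35.5)),
                  grid = sim$stack$grid)
probs <- extract_at_sites(lapply(fits, `[[`, "overall"), sim$stack$grid, sites)
thr <- threshold_rule("fixed", names(fits), fixed_value = 0.4)
menu <- build_menu(apply_threshold(probs, thr), sim$traits,
                   selected_traits = c("growth_form", "bloom_months",
                                       "pollinator_count"),
                   include_all = TRUE)
print(menu, digits = 3)
#>   species_id siteA siteB min_probability threshold included growth_form
#> 1       vs01 0.622 0.490           0.490       0.4     TRUE       grass
#> 2       vs02 0.219 0.519           0.219       0.4    FALSE       grass
#>      bloom_months pollinator_count
#> 1 Jan-Feb-Mar-Apr               27
#> 2 Apr-May-Jun-Jul               27
```

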