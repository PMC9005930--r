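---
title: "Ensemble habitat models and seed menus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble habitat models and seed menus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical procedure implemented by
`seedmenus`, the assumptions behind it, the tunable parameters, the design
choices made where several defensible options existed, and what the
package's synthetic-data validation does and does not demonstrate.

## 1. The modelling problem

Occurrence records for desert plants are presence-only: herbarium
specimens, vegetation plots and seed-collection vouchers record where a
species *was seen*, never where it is absent. The package models the
probability of suitable habitat on a projected 1-km grid from a stack of
standardized environmental covariates (the fourteen recognised codes cover
seasonal precipitation, temperature extremes and range, an annual
heat–moisture index, climatic moisture deficit, two NDVI canopy metrics,
soil water stress, surface texture, heat load, slope and a topographic
position index). Only the heat–moisture index has an internal formula,
`AHM = (MAT + 10) / (MAP / 1000)`; every other covariate is consumed as a
prepared raster because their derivations depend on external climate and
satellite products.

## 2. Occurrence preparation

* **Quality control** (`qc_filter`): records with positional uncertainty
  above 1 km (the modelling resolution) are removed; records with *missing*
  uncertainty are kept, since the error is only known when metadata say so.
  Records outside the grid, on masked cells, or on water cells are removed,
  and the counts per rule are reported.
* **Rasterization** (`rasterize_presences`): one presence per occupied
  cell, whatever the record multiplicity.
* **Spatial thinning** (`thin_presences`): the grid is partitioned into
  blocks anchored at the grid origin and at most 3 presence cells are kept
  per block, uniformly at random. We interpret the thinning area as a
  10 km × 10 km block rather than a literal 10-km² (3.16-km) square; at
  landscape scale that matches how grid-sampling is normally applied, and
  the block size is a parameter (`block_km`) for users who read it the
  other way.
* **Pseudo-absences** (`sample_pseudo_absences`): uniform draws without
  replacement from valid cells. Following the large-sample recommendations
  for presence-background modelling, the additive and maximum-entropy
  families get 10,000 points (background for the latter, which therefore
  keeps presence cells in the draw) and the tree ensemble gets as many
  absences as presences, excluding presence cells. Requests above the
  available cells are capped with a warning — on desk-scale grids the cap
  binds almost always, which is intended.

## 3. The three learners

All learners implement one contract: fit from covariate tables, predict
suitability in [0, 1], expose an effective parameter count, a per-term
complexity, and a raw per-variable importance. Fits are deterministic
given data and seed.

* **Penalized additive model**: binomial GAM with one univariate thin-plate
  regression spline per covariate (basis size `gam_k = 10`, reduced when a
  covariate has few unique values; constants enter with 0 degrees of
  freedom), REML smoothing and the extra shrinkage penalty that lets a term
  be penalized to approximately zero effective degrees of freedom (edf).
  Pseudo-absences are down-weighted so total absence weight equals total
  presence weight. Designs of 1500 rows or more are fit with the
  discretized fast-REML algorithm, which is numerically equivalent for
  these univariate smooths and roughly ten times faster; smaller designs
  use exact REML. Univariate smooths (no interactions) are assumed
  throughout, consistent with counting model complexity in "terms".
* **Tree ensemble**: a classification random forest, 1000 trees by
  default, presence-class vote fraction as suitability, permutation
  importance (mean decrease in accuracy) retained.
* **Maximum-entropy model**: authored in this package. Covariates are
  min–max scaled to [0, 1] on the training data and expanded into linear,
  quadratic, pairwise-product and forward/reverse hinge features (hinge
  knots at `n_hinge = 20` training quantiles). Coefficients are estimated
  by an L1-regularized weighted logistic regression along a 200-step
  decreasing lambda path with background points weighted 100:1, taking the
  endpoint of the path — the standard infinitely-weighted-logistic
  formulation of the maximum-entropy density model. Per-feature
  regularization shrinks with the number of presences: linear/quadratic/
  product features get an interpolated base rate (1.0 at 10 presences down
  to 0.05 at 100+) times the feature's standard deviation, divided by
  sqrt(n presences); hinge features get a flat 0.5/sqrt(n presences). The
  flat hinge rate matters: scaling hinge penalties by their (small)
  standard deviations lets rarely-activated hinges overfit pure noise. The
  raw output is exp(linear predictor) normalized to sum to 1 over the
  training background; the logistic output is c·q/(1 + c·q) with
  c = exp(entropy of the raw background distribution). Exact numerical
  equivalence with any particular external MaxEnt build is a non-goal; the
  conformance tests assert the behaviours that matter (normalization,
  flatness under no information, sign recovery, regularization path
  determinism).

## 4. Evaluation and cross-validation

Each model spec is evaluated over `n_runs` cross-validation runs (default
50). A run draws a *fresh* thinned presence set and *fresh* pseudo-absences
(sub-seeded deterministically from the master seed), withholds a stratified
20 % of presences and of absences, fits on the remainder and evaluates on
the holdout:

* **AUC** as the Mann–Whitney pair statistic (wins + half-ties over all
  presence × absence pairs);
* **TSS** = sensitivity + specificity − 1, reported at the threshold that
  maximizes sensitivity + specificity on that run's holdout (the procedure
  never states a fixed classification threshold, and max-SSS is the
  standard choice; the scan is exhaustive over midpoints of adjacent
  distinct scores plus {0, 1}, returning the smallest maximizer);
* the **continuous Boyce index**: 101 moving windows of width 0.1 across
  [0, 1]; per window, the ratio of the presence fraction to the background
  fraction (windows with zero background are skipped); the index is the
  Spearman correlation of window midpoint with that ratio. With
  non-overlapping windows this reduces to the classical binned form, and a
  quantile-bin mode is available (in that mode the index is invariant to
  monotone transforms of the scores). Overlapping windows make single null
  draws noisy (sd ≈ 0.3); judgements about the null are made on averages.
* **AICc**, where a likelihood exists: for the maximum-entropy family the
  log-likelihood is the sum over presences of the log normalized raw
  output, K is the number of nonzero coefficients, and n is the number of
  presences; for the additive family the binomial deviance with total edf
  as K. n ≤ K + 1 yields +Inf (excluded from ranking); the forest reports
  NA.

Holdout splits are stratified by class to prevent single-class holdouts at
small sample sizes; a degenerate split is redrawn a bounded number of
times.

## 5. Candidate selection and ensembling

The model space is every non-empty covariate subset of at most
`max_terms = 6`, excluding any pair with |Pearson r| > 0.7 computed once
per species on the full stack and applied identically to all three
families. When both NDVI codes are present, annual species may not use the
NDVI maximum and perennials may not use the NDVI amplitude. Full
enumeration of 14 covariates gives 6,475 specs; `spec_cap` takes a seeded
uniform subsample for desk-scale runs.

Selection per family (`select_candidates`): keep specs with mean
Boyce > 0, mean AUC > 0.5 and mean TSS > 0; rank by mean TSS; within
clusters of near-equal TSS (|ΔTSS| < 0.01) prefer lower mean AICc where
available; keep the top `n_keep = 10`. This committed decision rule is one
reading of "consider several accuracy metrics"; every element is a
parameter. If nothing passes, the single best-TSS spec is kept with a
warning. Candidate weights are proportional to mean TSS.

Each candidate's prediction layer is the mean of its per-run fits'
predictions; the family ensemble is the TSS-weighted cellwise mean of
candidate layers (hence convex in them); the overall ensemble is the plain
mean of the family ensembles. The uncertainty layer is the cellwise sample
standard deviation across *all* candidates from all families divided by
sqrt(m) — reading "standard error" as the error of the ensemble mean — with
plain SD available via `se_mode = "sd"`.

Relative importance: per family, raw importances (edf / mean decrease in
accuracy / permutation importance) are averaged over the candidates
containing each code (absent codes score 0), normalized to 100 within the
family, averaged across families and renormalized to 100. The
cross-family recipe is an interpretation chosen because it produces rows
summing to ~100, matching the structure of published per-species tables.
Response curves sweep each top-ranked code over its observed range with
other covariates at training means (additive/maxent) or by data-averaged
partial dependence (forest), weighted-averaging candidates within family
and pooling across families.

## 6. Seed menus

Sites are points or single-ring polygons (multipart polygons are rejected
with guidance, as they conflate spatially distinct sites). Points read
their containing cell; polygons summarise the valid cells whose centres
fall inside, by mean (default; least surprising), min (the conservative
variant) or max. Inclusion uses the inclusive comparison — probability
**≥** threshold — at **every** site, so menus are monotone: raising a
threshold or adding a site can only remove species. Menus report per-site
probabilities *and* their minimum, join the selected trait columns, and
flag species missing from the trait table rather than dropping them. The
coverage map counts, per cell, the species at or above their thresholds;
it equals the menu engine applied to every cell as a site.

## 7. Bias diagnostic

Aggregated habitat probability and SE layers (cellwise means across
species) are regressed on Euclidean distance to developed-feature cells
(exact two-pass squared distance transform over cell centres) using a
univariate penalized thin-plate smooth with ~10 basis functions; the
report is R² = 1 − SSE/SST over all valid cells plus an 8-equal-width-bin
summary (n, mean, quartiles per distance class). All valid cells are used
by default; regression on a subsample is a caller-side option at larger
grids. Zero-variance responses return an undefined flag rather than 0.

## 8. Synthetic data: what it emulates, what it does not

Covariate layers are Gaussian-kernel-smoothed white noise (the
autocorrelation range is the kernel radius in cells), standardized to zero
mean and unit variance; requested pairwise correlations are imposed by
exact linear mixing after generation. Virtual species are logistic in a
subset of covariates, giving exact ground truth at every cell. Occurrences
are drawn with replacement with probability proportional to true
probability times exp(bias × access score), with within-cell coordinate
jitter and truncated-normal positional uncertainties; road networks are
straight transects and the access score is standardized negative distance
to them.

This emulates spatial autocorrelation, niche structure, uneven sampling
and accessibility bias. It does **not** emulate non-stationary responses,
dispersal limitation, biotic interactions, observation-date effects,
taxonomic error, or covariates with realistic marginal distributions
(everything is Gaussian). Passing validation therefore demonstrates that
the machinery recovers known generating structure under its own
assumptions — not that any particular real species is modelled well.

## 9. Validation experiments and problem sizes

* **Parameter recovery** (`recovery_experiment`): 64 × 64 grid, 8
  covariates (autocorrelation range 6), one species with coefficients +3
  (summer precipitation) and −2.5 (summer maximum temperature), logit
  intercept −2 (≈ 25 % prevalence), 500 occurrence records; pipeline at
  `max_terms = 4`, a seeded cap of 30 specs per family, 10 CV runs,
  `n_keep = 5`. Held-out AUC is measured on an independent Bernoulli
  realization of the species — realized presence versus realized absence
  cells — the standard virtual-species protocol. (Scoring against uniform
  random background instead caps AUC near 0.78 *for the true probability
  itself* at this prevalence, so that variant measures prevalence, not
  model quality.) At these settings the ensemble reaches AUC ≈ 0.92
  against a true-model ceiling of ≈ 0.95, and the two causal covariates
  take the top-2 importance ranks by a wide margin.
* **Bias sensitivity** (`bias_experiment`): one 64 × 64 landscape
  (range 4), 4 roads, 4 species × 300 records, sampled once unbiased and
  once with access-bias strength 5, pipeline at `max_terms = 2`, cap 8,
  4 runs, `n_keep = 3`. Smaller or smoother nulls (e.g. 48 × 48 with
  range 6 and 2 species) are unusable: the aggregate and the distance
  field are both low-frequency surfaces, so their spurious R² routinely
  exceeds 5 %. Even at this size the biased-minus-unbiased gap is modest,
  because grid thinning genuinely removes much of the induced clustering —
  the same mitigation argued for in the field's workflow.

These sizes were chosen so the full validation completes in minutes on a
single CPU while leaving each check a real test; the pipeline defaults
(50 runs, 6 terms, 10 candidates) remain the production settings.

## 10. Numerical choices and degenerate inputs

* Coordinates are projected km; cell centres define coordinates; row 1 is
  the northern edge; cells are half-open, making the index ↔ coordinate
  maps exact inverses.
* Raster stacks serialize to a self-describing JSON text format at 17
  significant digits, which round-trips doubles bit-exactly.
* A constant covariate layer has *undefined* correlations (NA), never 0;
  the enumeration treats NA as "not forbidden".
* Max-SSS threshold scans return the *smallest* maximizing threshold
  (deterministic tie-break).
* One master seed fans out to per-species, per-run, per-draw sub-seeds via
  a documented string-hash (`fanout_seed`), keeping every stage
  independently reproducible and below 2^31.
* Degenerate cases: empty occurrence sets pass QC (empty output, zero
  counts); single-candidate SE layers are zero with a warning;
  single-class holdouts are redrawn; maxent with all-constant covariates
  errors ("no usable features"); AICc with n ≤ K + 1 is +Inf and excluded
  from tie-breaks.

## 11. Known limitations

* No spatially blocked cross-validation (random holdouts only).
* No reprojection: all inputs must share one grid.
* The maximum-entropy learner approximates, and does not numerically
  reproduce, external MaxEnt implementations.
* The trait generator uses a fixed 10-column vocabulary with uniform
  categorical draws; it supports join/menu logic, not trait realism.
* Polygon extraction uses cell-centre membership; slivers that touch a
  cell without containing its centre do not count.
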