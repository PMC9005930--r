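test_that("landscape generation is deterministic, standardized and finite", {
  a <- make_landscape(16, 16, n_covariates = 3, autocorrelation_range = 3, seed = 7)
  b <- make_landscape(16, 16, n_covariates = 3, autocorrelation_range = 3, seed = 7)
  expect_identical(a$layers, b$layers)
  for (code in names(a$layers)) {
    v <- stack_values(a)[[code]]
    expect_true(all(is.finite(v)))
    expect_equal(mean(v), 0, tolerance = 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-10)
  }
})

test_that("requested pairwise correlations are achieved", {
  st <- make_landscape(64, 64, n_covariates = 2, autocorrelation_range = 10,
                       correlation_pairs = list(list("SP", "WP", 0.9)), seed = 1)
  r <- correlation_matrix(st)
  expect_gte(r["SP", "WP"], 0.8)
  expect_lte(r["SP", "WP"], 1.0)
  expect_equal(r["SP", "WP"], 0.9, tolerance = 0.01)
})

test_that("unachievable or duplicated correlation requests error", {
  expect_error(make_landscape(8, 8, n_covariates = 3, seed = 1,
    correlation_pairs = list(list("SP", "WP", 1.5))), "positive semi-definite")
  expect_error(make_landscape(8, 8, n_covariates = 3, seed = 1,
    correlation_pairs = list(list("SP", "WP", 0.5), list("WP", "Tmax", 0.5))),
    "more than one pair")
  expect_error(make_landscape(8, 8, codes = c("SP", "SP"), seed = 1), "duplicate")
})

test_that("virtual species probability matches the logistic closed form", {
  st <- make_landscape(12, 12, n_covariates = 2, seed = 3)
  vs <- make_virtual_species(st, c("SP", "WP"), c(1.5, -0.7), intercept = 0.2)
  eta <- 0.2 + 1.5 * st$layers$SP + (-0.7) * st$layers$WP
  expect_lt(max(abs(vs$true_probability - 1 / (1 + exp(-eta)))), 1e-12)
  # zero coefficients -> constant 0.5; strong negative intercept -> ~0
  vs0 <- make_virtual_species(st, "SP", 0, intercept = 0)
  expect_true(all(vs0$true_probability == 0.5))
  vsneg <- make_virtual_species(st, "SP", 2, intercept = -50)
  expect_lt(max(vsneg$true_probability), 1e-10)
  expect_error(make_virtual_species(st, "NOPE", 1), "unknown covariate")
})

test_that("inverse logit at a unit covariate value follows the closed form", {
  st <- toy_stack(SP = matrix(1, 4, 4))
  vs <- make_virtual_species(st, "SP", 2, intercept = 0)
  expect_equal(vs$true_probability[1, 1], 1 / (1 + exp(-2)), tolerance = 1e-12)
})

test_that("unbiased occurrence sampling on a flat species is uniform", {
  st <- make_landscape(8, 8, n_covariates = 1, seed = 5)
  vs <- make_virtual_species(st, "SP", 0, intercept = 0)   # constant probability
  occ <- sample_occurrences(vs, 5000, seed = 11)
  cells <- xy_cell(st$grid, occ$x, occ$y)
  counts <- tabulate(cells, nbins = 64)
  p <- chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("access bias shifts sampling towards accessible cells", {
  st <- make_landscape(16, 16, n_covariates = 1, seed = 5)
  vs <- make_virtual_species(st, "SP", 0, intercept = 0)
  roads <- make_roads_mask(st$grid, seed = 6)
  access <- access_from_distance(distance_to_features(roads))
  o0 <- sample_occurrences(vs, 400, 0, seed = 12)
  o5 <- sample_occurrences(vs, 400, 5, access_raster = access, seed = 12)
  m0 <- mean(access[xy_cell(st$grid, o0$x, o0$y)])
  m5 <- mean(access[xy_cell(st$grid, o5$x, o5$y)])
  expect_gt(m5, m0)
})

test_that("occurrence sampling validates inputs and is deterministic", {
  st <- make_landscape(8, 8, n_covariates = 1, seed = 5)
  vs <- make_virtual_species(st, "SP", 1, intercept = 0)
  expect_error(sample_occurrences(vs, 0), "n_target")
  expect_error(sample_occurrences(vs, 10, access_bias_strength = 2), "access_raster")
  expect_identical(sample_occurrences(vs, 50, seed = 3),
                   sample_occurrences(vs, 50, seed = 3))
})

test_that("trait tables have the ten attribute columns and are reproducible", {
  tt <- make_trait_table(c("a", "b", "c"), seed = 2)
  expect_equal(nrow(tt), 3)
  expect_setequal(names(tt),
    c("species_id", "growth_form", "lifespan", "bloom_months", "pollinator_count",
      "larval_host", "adult_host", "tortoise_forage", "tortoise_cover",
      "known_colonizer", "propagation_method"))
  expect_false(anyNA(tt))
  expect_identical(tt, make_trait_table(c("a", "b", "c"), seed = 2))
  expect_error(make_trait_table(character(0)), "non-empty")
  expect_error(make_trait_table(c("a", "a")), "duplicate")
})

test_that("packaged 49-species performance fixture matches printed values", {
  t2 <- load_table2_fixture()
  expect_equal(nrow(t2), 49)
  expect_true(all(t2$auc >= 0 & t2$auc <= 1))
  expect_true(all(t2$tss >= 0 & t2$tss <= 1))
  imp <- as.matrix(t2[fixture_importance_codes()])
  expect_true(all(imp >= 0))
  lo <- t2[t2$species == "Lupinus odoratus", ]
  expect_equal(lo$n, 45); expect_equal(lo$auc, 0.97); expect_equal(lo$tss, 0.919)
  ad <- t2[t2$species == "Ambrosia dumosa", ]
  expect_equal(ad$n, 2524); expect_equal(ad$auc, 0.822); expect_equal(ad$tss, 0.496)
})
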