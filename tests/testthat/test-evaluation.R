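test_that("AUC equals the brute-force pairwise statistic on random instances", {
  expect_equal(auc(c(0.9, 0.8, 0.4), c(0.7, 0.3, 0.2)), 8 / 9)
  expect_equal(auc(c(0.8, 0.9), c(0.1, 0.2)), 1.0)
  expect_equal(auc(c(0.3, 0.5), c(0.3, 0.5)), 0.5)
  set.seed(55)
  for (i in 1:200) {
    np <- sample(1:8, 1); nn <- sample(1:8, 1)
    pos <- sample(seq(0, 1, 0.1), np, replace = TRUE)
    neg <- sample(seq(0, 1, 0.1), nn, replace = TRUE)
    expect_equal(auc(pos, neg), brute_auc(pos, neg), tolerance = 1e-12)
  }
  expect_error(auc(numeric(0), 1), "non-empty")
})

test_that("TSS at a threshold matches the confusion matrix and its identity", {
  m <- tss_at(c(1, 1, 0, 0), c(0.9, 0.6, 0.55, 0.1), 0.5)
  expect_equal(m$sensitivity, 1.0)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$tss, 0.5)
  # all predicted presence at threshold 0
  m0 <- tss_at(c(1, 1, 0, 0), c(0.9, 0.6, 0.55, 0.1), 0)
  expect_equal(m0$tss, 0)
  expect_error(tss_at(c(1, 0), c(0.2, 0.4), 1.5), "threshold")
  expect_error(tss_at(c(1, 1), c(0.2, 0.4), 0.5), "classes")
  # identity holds on random cases
  set.seed(4)
  for (i in 1:25) {
    lab <- c(1, 0, rbinom(20, 1, 0.4))
    sc <- runif(22)
    m <- tss_at(lab, sc, runif(1))
    expect_equal(m$tss, m$sensitivity + m$specificity - 1, tolerance = 1e-12)
  }
})

test_that("max-SSS threshold equals dense-grid brute force", {
  m <- max_sss_threshold(c(1, 1, 0, 0), c(0.9, 0.6, 0.55, 0.1))
  expect_equal(m$threshold, 0.575)
  expect_equal(m$tss, 1.0)
  # one distinct score: TSS 0 at every threshold
  m1 <- max_sss_threshold(c(1, 0, 1), c(0.4, 0.4, 0.4))
  expect_equal(m1$tss, 0)
  set.seed(8)
  for (i in 1:10) {
    lab <- c(1, 0, rbinom(48, 1, 0.5))
    sc <- round(runif(50), 3)
    got <- max_sss_threshold(lab, sc)
    grid_tss <- vapply(seq(0, 1, length.out = 10001),
                       function(t) tss_at(lab, sc, t)$tss, 0)
    expect_equal(got$tss, max(grid_tss), tolerance = 1e-9)
  }
})

test_that("Boyce index reproduces the fixed-bin hand computation", {
  b <- boyce_index(c(0.1, 0.5, 0.9, 0.9), c(0.1, 0.2, 0.4, 0.5, 0.7, 0.9),
                   n_windows = 3, window_width = 1 / 3)
  # P/E = {0.75, 0.75, 1.5}; Spearman of (1.5, 1.5, 3) vs (1, 2, 3)
  expect_equal(b, 0.8660254, tolerance = 1e-6)
})

test_that("Boyce index is 1 for monotone P/E and ~0 under the null", {
  # presences concentrated at high suitability -> strictly increasing P/E
  set.seed(10)
  bg <- runif(2000)
  pres <- sqrt(runif(2000))   # density increasing in suitability
  expect_gt(boyce_index(pres, bg), 0.95)
  # presences sampled exactly proportional to background -> index ~ 0 on
  # average (single draws are noisy because the moving windows overlap)
  nulls <- vapply(1:6, function(i) {
    set.seed(100 + i)
    boyce_index(sample(bg, 1000), bg)
  }, 0)
  expect_lt(abs(mean(nulls)), 0.3)
})

test_that("quantile-mode Boyce is invariant to monotone score transforms", {
  set.seed(12)
  bg <- runif(800); pres <- runif(300)^0.7
  b1 <- boyce_index(pres, bg, n_windows = 10, mode = "quantile")
  squash <- function(x) x^3          # strictly monotone on [0,1]
  b2 <- boyce_index(squash(pres), squash(bg), n_windows = 10, mode = "quantile")
  expect_equal(b1, b2, tolerance = 1e-9)
})

test_that("AICc follows the closed form for uniform raw output and increases in K", {
  # uninformative covariate -> all features regularized out -> uniform raw
  # over the B background points, so lnL = n * ln(1/B)
  set.seed(2)
  u <- data.frame(SP = runif(120))
  f <- fit_sdm("SP", u[1:20, , drop = FALSE], u[21:120, , drop = FALSE], "maxent_like")
  expect_equal(max(predict(f, u, type = "raw")) / min(predict(f, u, type = "raw")), 1)
  n <- 20; B <- 100
  lnL <- n * log(1 / B)
  K <- max(parameter_count(f), 1)
  expect_equal(aicc(f, u[1:20, , drop = FALSE]),
               2 * K - 2 * lnL + 2 * K * (K + 1) / (n - K - 1), tolerance = 1e-9)
  # AICc strictly increases with K at fixed lnL
  a <- vapply(1:10, function(K) 2 * K - 2 * lnL + 2 * K * (K + 1) / (n - K - 1), 0)
  expect_true(all(diff(a) > 0))
  expect_true(is.na(aicc(structure(list(family = "tree_ensemble"), class = "sdm_fit"))))
})

test_that("cross-validation is deterministic, averages its runs, and finds signal", {
  sig <- signal_fixture()
  # a sharply delimited species so that block-thinned training sets (at
  # most 3 presences per 10-km block) still carry the signal
  vs <- make_virtual_species(sig$stack, c("SP", "Tmax"), c(4, -4), intercept = -4)
  cells <- rasterize_presences(sample_occurrences(vs, 500, seed = 61), sig$stack$grid)
  cfg <- pipeline_config(n_runs = 4)
  cv1 <- suppressWarnings(
    cross_validate(c("SP", "Tmax"), "smooth_additive", sig$stack, cells,
                   n_runs = 4, seed = 5, config = cfg))
  cv2 <- suppressWarnings(
    cross_validate(c("SP", "Tmax"), "smooth_additive", sig$stack, cells,
                   n_runs = 4, seed = 5, config = cfg))
  expect_identical(cv1$runs, cv2$runs)
  expect_equal(nrow(cv1$runs), 4)
  expect_equal(cv1$mean[["auc"]], mean(cv1$runs$auc))
  expect_gte(cv1$mean[["auc"]], 0.8)
  expect_equal(cv1$runs$tss,
               cv1$runs$sensitivity + cv1$runs$specificity - 1, tolerance = 1e-12)
})
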