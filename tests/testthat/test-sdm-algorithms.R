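families <- c("smooth_additive", "tree_ensemble", "maxent_like")

test_that("all learners satisfy the shared contract (range, determinism, classes)", {
  sig <- signal_fixture()
  pres <- sig$presence[1:60, ]
  bg <- sig$background[1:300, ]
  newdata <- sig$background[301:400, ]
  for (fam in families) {
    f1 <- fit_sdm(c("SP", "Tmax"), pres, bg, fam, seed = 42,
                  control = list(n_trees = 200, n_hinge = 10))
    f2 <- fit_sdm(c("SP", "Tmax"), pres, bg, fam, seed = 42,
                  control = list(n_trees = 200, n_hinge = 10))
    p1 <- predict(f1, newdata); p2 <- predict(f2, newdata)
    expect_identical(p1, p2)
    expect_true(all(p1 >= 0 & p1 <= 1))
    expect_error(fit_sdm(c("SP", "Tmax"), pres[0, ], bg, fam), "required")
    expect_error(fit_sdm(c("SP", "Tmax"), pres, bg[0, ], fam), "required")
  }
})

test_that("every family recovers a strong synthetic signal (held-out AUC >= 0.8)", {
  sig <- signal_fixture()
  n <- nrow(sig$presence)
  set.seed(77)
  hold <- sample(n, round(0.25 * n))
  bhold <- sample(nrow(sig$background), 400)
  ahold <- sample(nrow(sig$absence), round(0.25 * nrow(sig$absence)))
  for (fam in families) {
    # each family trains on its own pseudo-absence protocol
    bg <- if (fam == "tree_ensemble") sig$absence[-ahold, ] else sig$background[-bhold, ]
    f <- fit_sdm(c("SP", "Tmax"), sig$presence[-hold, ], bg,
                 fam, seed = 1, control = list(n_trees = 500))
    a <- auc(predict(f, sig$presence[hold, ]), predict(f, sig$background[bhold, ]))
    expect_gte(a, 0.8)
  }
})

test_that("shrinkage drives noise and constant smooth terms towards zero edf", {
  sig <- signal_fixture()
  f <- fit_sdm(c("SP", "WP"), sig$presence, sig$background, "smooth_additive", seed = 3)
  expect_gt(term_complexity(f, "SP"), term_complexity(f, "WP"))  # WP is noise here
  pres <- sig$presence; bg <- sig$background
  pres$Tmin <- 1; bg$Tmin <- 1                                   # constant covariate
  fc <- fit_sdm(c("SP", "Tmin"), pres, bg, "smooth_additive", seed = 3)
  expect_lt(term_complexity(fc, "Tmin"), 0.1)
  expect_true("Tmin" %in% fc$meta$dropped)
})

test_that("random forest separates separable data and is null on shuffled labels", {
  x <- data.frame(SP = c(rnorm(100, -2), rnorm(100, 2)))
  pres <- x[101:200, , drop = FALSE]; bg <- x[1:100, , drop = FALSE]
  f <- fit_sdm("SP", pres, bg, "tree_ensemble", seed = 5, control = list(n_trees = 300))
  expect_equal(auc(predict(f, pres), predict(f, bg)), 1.0)
  # permuted labels: held-out AUC ~ 0.5
  set.seed(9)
  pool <- data.frame(SP = rnorm(500))
  lab <- sample(rep(0:1, each = 250))
  train <- 1:400; test <- 401:500
  fp <- fit_sdm("SP", pool[train, , drop = FALSE][lab[train] == 1, , drop = FALSE],
                pool[train, , drop = FALSE][lab[train] == 0, , drop = FALSE],
                "tree_ensemble", seed = 5, control = list(n_trees = 300))
  sc <- predict(fp, pool[test, , drop = FALSE])
  a <- auc(sc[lab[test] == 1], sc[lab[test] == 0])
  expect_lt(abs(a - 0.5), 0.1)
})

test_that("maxent raw output is normalized and flat without information", {
  sig <- signal_fixture()
  f <- fit_sdm(c("SP", "Tmax"), sig$presence, sig$background, "maxent_like", seed = 2)
  raw <- predict(f, sig$background, type = "raw")
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  # uninformative uniform covariate: regularization zeroes every feature,
  # leaving an exactly flat raw distribution
  set.seed(30)
  u <- data.frame(SP = runif(220))
  fu <- fit_sdm("SP", u[1:20, , drop = FALSE], u[21:220, , drop = FALSE],
                "maxent_like", seed = 2)
  ru <- predict(fu, u[21:220, , drop = FALSE], type = "raw")
  expect_lt(max(ru) / min(ru), 1.01)
  # fully constant covariates are an error (no usable features)
  k <- data.frame(SP = rep(0.5, 40))
  expect_error(fit_sdm("SP", k[1:10, , drop = FALSE], k[11:40, , drop = FALSE],
                       "maxent_like"), "constant")
})

test_that("maxent linear coefficient sign follows a monotone presence gradient", {
  set.seed(21)
  bg <- data.frame(SP = runif(400))
  pres <- data.frame(SP = runif(150, 0.7, 1))   # presences at high SP
  f <- fit_sdm("SP", pres, bg, "maxent_like", seed = 8, control = list(n_hinge = 5))
  expect_gt(unname(f$fit$beta["lin_SP"]), 0)
  expect_gt(parameter_count(f), 0)
  # prediction increases with SP
  sweep <- data.frame(SP = c(0.1, 0.9))
  pr <- predict(f, sweep)
  expect_gt(pr[2], pr[1])
})

test_that("parameter counts and term complexity follow family semantics", {
  sig <- signal_fixture()
  pres <- sig$presence[1:50, ]; bg <- sig$background[1:200, ]
  fg <- fit_sdm("SP", pres, bg, "smooth_additive", seed = 1)
  expect_gt(parameter_count(fg), 0)
  fr <- fit_sdm("SP", pres, bg[1:50, ], "tree_ensemble", seed = 1,
                control = list(n_trees = 100))
  expect_true(is.na(parameter_count(fr)))
  expect_true(is.na(term_complexity(fr, "SP")))
  imp <- sdm_importance(fr)
  expect_named(imp, "SP")
  expect_gte(imp[["SP"]], 0)
})
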