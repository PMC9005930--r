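# Three pluggable presence/background learners behind one fitting
# contract: fit on covariate tables, predict suitability in [0, 1],
# report parameter counts, per-term complexity, and variable importance.
#
# - smooth_additive: binomial GAM with one penalized univariate smooth per
#   variable, REML smoothing and an extra shrinkage penalty so terms can be
#   penalized to ~0 effective degrees of freedom (mgcv).
# - tree_ensemble: classification random forest, presence-class vote
#   fraction as suitability (randomForest).
# - maxent_like: maximum-entropy presence/background model, implemented as
#   an L1-regularized logistic model over a linear/quadratic/product/hinge
#   feature expansion (glmnet path), with raw output normalized over the
#   training background.

#' Fit one SDM under the shared contract
#'
#' @param variables covariate codes used as predictors.
#' @param presence data frame of covariate values at presence cells.
#' @param background data frame of covariate values at pseudo-absence /
#'   background cells.
#' @param family `"smooth_additive"`, `"tree_ensemble"` or `"maxent_like"`.
#' @param seed integer seed (fits are deterministic under it).
#' @param control list of family hyperparameters: `n_trees` (default 1000),
#'   `gam_k` (smooth basis size, default 10), `regmult` (maxent
#'   regularization multiplier, default 1), `n_hinge` (hinge knots per
#'   variable, default 20).
#' @return an object of class `sdm_fit`.
#' @export
fit_sdm <- function(variables, presence, background,
                    family = c("smooth_additive", "tree_ensemble", "maxent_like"),
                    seed = 1, control = list()) {
  family <- match.arg(family)
  switch(family,
    smooth_additive = fit_smooth_additive(variables, presence, background,
                                          k = control$gam_k %||% 10, seed = seed),
    tree_ensemble = fit_tree_ensemble(variables, presence, background,
                                      n_trees = control$n_trees %||% 1000, seed = seed),
    maxent_like = fit_maxent_like(variables, presence, background,
                                  regmult = control$regmult %||% 1,
                                  n_hinge = control$n_hinge %||% 20, seed = seed))
}

check_classes <- function(presence, background) {
  if (!nrow(presence) || !nrow(background))
    stopf("both presences and absences/background are required")
}

#' Penalized additive presence/absence model
#'
#' Binomial GAM with one univariate penalized regression spline per
#' variable (basis size `k`), REML smoothing-parameter selection and an
#' extra shrinkage penalty allowing smooth terms to be penalized to zero.
#' Pseudo-absences are down-weighted so total absence weight equals total
#' presence weight.  Covariates with too few unique values enter linearly;
#' constant covariates are dropped (effective degrees of freedom 0).
#'
#' @inheritParams fit_sdm
#' @param k basis dimension per smooth term.
#' @export
fit_smooth_additive <- function(variables, presence, background, k = 10, seed = 1) {
  check_classes(presence, background)
  np <- nrow(presence); nb <- nrow(background)
  data <- rbind(presence[variables], background[variables])
  data$label <- c(rep(1L, np), rep(0L, nb))
  w <- c(rep(1, np), rep(np / nb, nb))
  terms <- character(0); dropped <- character(0)
  for (v in variables) {
    u <- length(unique(data[[v]]))
    if (u < 2) { dropped <- c(dropped, v); next }
    kk <- min(k, u - 1)
    terms <- c(terms, if (kk >= 4) sprintf("s(%s, k = %d, bs = \"tp\")", v, kk) else v)
  }
  if (!length(terms)) stopf("singular design: all covariates are constant")
  fml <- stats::as.formula(paste("label ~", paste(terms, collapse = " + ")))
  set.seed(seed)
  # large designs: discretized fast-REML fitting, numerically equivalent
  # for these univariate smooths and an order of magnitude faster
  fit <- if (nrow(data) >= 1500)
    mgcv::bam(fml, family = stats::binomial(), data = data, weights = w,
              method = "fREML", select = TRUE, discrete = TRUE)
  else
    mgcv::gam(fml, family = stats::binomial(), data = data, weights = w,
              method = "REML", select = TRUE)
  structure(list(family = "smooth_additive", variables = variables, fit = fit,
                 meta = list(dropped = dropped, n_presence = np, n_background = nb,
                             train_means = vapply(data[variables], mean, 0))),
            class = c("sdm_fit_gam", "sdm_fit"))
}

#' Random-forest presence/absence model
#'
#' Classification forest (default 1000 trees) with permutation importance
#' retained; suitability is the presence-class vote fraction.
#' @inheritParams fit_sdm
#' @param n_trees number of trees (>= 1).
#' @export
fit_tree_ensemble <- function(variables, presence, background, n_trees = 1000, seed = 1) {
  check_classes(presence, background)
  if (n_trees < 1) stopf("n_trees must be >= 1")
  x <- rbind(presence[variables], background[variables])
  y <- factor(c(rep(1L, nrow(presence)), rep(0L, nrow(background))), levels = c("0", "1"))
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = n_trees, importance = TRUE)
  structure(list(family = "tree_ensemble", variables = variables, fit = fit,
                 meta = list(n_presence = nrow(presence), n_background = nrow(background),
                             train_means = vapply(x, mean, 0),
                             train_data = x)),
            class = c("sdm_fit_rf", "sdm_fit"))
}

# ---- maxent-like learner ---------------------------------------------------

# Feature expansion: each variable is min-max scaled to [0,1] over the
# training data, then expanded into linear, quadratic, pairwise-product and
# forward/reverse hinge features (knots at training quantiles).
maxent_feature_spec <- function(variables, data, n_hinge) {
  spec <- list(variables = variables, n_hinge = n_hinge,
               lo = vapply(data[variables], min, 0),
               hi = vapply(data[variables], max, 0), knots = list())
  for (v in variables) {
    rng <- spec$hi[[v]] - spec$lo[[v]]
    if (rng <= 0) next
    q <- unique(stats::quantile((data[[v]] - spec$lo[[v]]) / rng,
                                probs = seq_len(n_hinge) / (n_hinge + 1), names = FALSE))
    spec$knots[[v]] <- q
  }
  spec
}

maxent_features <- function(spec, data) {
  cols <- list()
  scaled <- list()
  for (v in spec$variables) {
    rng <- spec$hi[[v]] - spec$lo[[v]]
    if (rng <= 0) next
    z <- pmin(1, pmax(0, (data[[v]] - spec$lo[[v]]) / rng))
    scaled[[v]] <- z
    cols[[paste0("lin_", v)]] <- z
    cols[[paste0("quad_", v)]] <- z^2
  }
  vs <- names(scaled)
  if (length(vs) >= 2) {
    for (i in seq_len(length(vs) - 1)) for (j in seq(i + 1, length(vs)))
      cols[[paste0("prod_", vs[i], "_", vs[j])]] <- scaled[[vs[i]]] * scaled[[vs[j]]]
  }
  for (v in vs) {
    for (t in spec$knots[[v]]) {
      if (t < 1) cols[[sprintf("hingef_%s_%.6f", v, t)]] <- pmax(0, scaled[[v]] - t) / (1 - t)
      if (t > 0) cols[[sprintf("hinger_%s_%.6f", v, t)]] <- pmax(0, t - scaled[[v]]) / t
    }
  }
  if (!length(cols)) stopf("no usable features: all covariates are constant")
  do.call(cbind, cols)
}

# Per-feature default regularization in the maximum-entropy tradition,
# shrinking with the number of presences: linear/quadratic/product
# features get an interpolated base rate times the feature's standard
# deviation over sqrt(n_presences); hinge features get a flat 0.5 /
# sqrt(n_presences) (not sd-scaled, so rarely-activated hinges are not
# under-penalized).
maxent_regularization <- function(X, np) {
  nm <- colnames(X)
  base <- stats::approx(x = c(10, 30, 100), y = c(1.0, 0.2, 0.05),
                        xout = min(max(np, 10), 100), rule = 2)$y
  sds <- apply(X, 2, stats::sd)
  reg <- base * sds
  reg[startsWith(nm, "hinge")] <- 0.5
  pmax(reg / sqrt(np), 1e-6)
}

#' Maximum-entropy-style presence/background model
#'
#' L1-regularized logistic model over a linear/quadratic/product/hinge
#' feature expansion, fit along a decreasing lambda path with background
#' points up-weighted (infinitely-weighted logistic regression).  Exposes
#' raw output (exponential of the linear predictor, normalized to sum to 1
#' over the training background) and a logistic-scaled output in \[0, 1\].
#'
#' @inheritParams fit_sdm
#' @param regmult regularization multiplier (1 = default strength).
#' @param n_hinge number of hinge knots per variable (at data quantiles).
#' @export
fit_maxent_like <- function(variables, presence, background, regmult = 1,
                            n_hinge = 20, seed = 1) {
  check_classes(presence, background)
  data <- rbind(presence[variables], background[variables])
  spec <- maxent_feature_spec(variables, data, n_hinge)
  X <- maxent_features(spec, data)
  np <- nrow(presence); nb <- nrow(background)
  y <- c(rep(1L, np), rep(0L, nb))
  w <- c(rep(1, np), rep(100, nb))
  reg <- maxent_regularization(X, np) * regmult
  lambda <- 10^seq(4, 0, length.out = 200) * mean(reg) * np / sum(w)
  old_fdev <- glmnet::glmnet.control()$fdev
  glmnet::glmnet.control(fdev = 0)   # fit the full path, no early stop
  on.exit(glmnet::glmnet.control(fdev = old_fdev), add = TRUE)
  set.seed(seed)
  fit <- glmnet::glmnet(X, y, family = "binomial", weights = w,
                        standardize = FALSE, penalty.factor = reg, lambda = lambda)
  beta <- as.numeric(fit$beta[, ncol(fit$beta)])
  names(beta) <- rownames(fit$beta)
  eta_bg <- as.numeric(X[y == 0, , drop = FALSE] %*% beta)
  m <- max(eta_bg)
  logZ <- m + log(sum(exp(eta_bg - m)))
  raw_bg <- exp(eta_bg - logZ)
  entropy <- -sum(raw_bg * log(pmax(raw_bg, 1e-300)))
  structure(list(family = "maxent_like", variables = variables,
                 fit = list(beta = beta, logZ = logZ, entropy = entropy, spec = spec),
                 meta = list(n_presence = np, n_background = nb, seed = seed,
                             train_means = vapply(data[variables], mean, 0),
                             train_data = data)),
            class = c("sdm_fit_maxent", "sdm_fit"))
}

# ---- shared contract -------------------------------------------------------

#' Predict suitability from a fitted SDM
#'
#' @param object an `sdm_fit`.
#' @param newdata data frame containing the fit's covariates.
#' @param type `"prob"` for suitability in \[0, 1\]; `"raw"`
#'   (maxent_like only) for output normalized over the training background.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.sdm_fit <- function(object, newdata, type = "prob", ...) {
  switch(object$family,
    smooth_additive = {
      p <- as.numeric(mgcv::predict.gam(object$fit, newdata = newdata, type = "response"))
      pmin(1, pmax(0, p))
    },
    tree_ensemble = {
      as.numeric(stats::predict(object$fit, newdata = newdata[object$variables],
                                type = "prob")[, "1"])
    },
    maxent_like = {
      X <- maxent_features(object$fit$spec, newdata)
      eta <- as.numeric(X %*% object$fit$beta[colnames(X)])
      raw <- exp(eta - object$fit$logZ)
      if (identical(type, "raw")) return(raw)
      cq <- exp(object$fit$entropy) * raw
      cq / (1 + cq)
    })
}

#' Number of effective parameters of a fitted SDM
#'
#' Smooth additive: total effective degrees of freedom; maxent-like:
#' coefficients with `|beta|` above a zero tolerance; tree ensemble: `NA`
#' (no likelihood-based complexity).
#' @param fit an `sdm_fit`.
#' @param tol zero tolerance for maxent coefficients.
#' @export
parameter_count <- function(fit, tol = 1e-7) {
  switch(fit$family,
    smooth_additive = sum(fit$fit$edf),
    maxent_like = sum(abs(fit$fit$beta) > tol),
    tree_ensemble = NA_real_)
}

#' Per-term complexity of a fitted SDM
#'
#' For the smooth additive family, the effective degrees of freedom of the
#' term for `code` (0 when the covariate was constant and dropped, 1 for a
#' linear term).  Other families return `NA`.
#' @param fit an `sdm_fit`.
#' @param code covariate code.
#' @export
term_complexity <- function(fit, code) {
  if (fit$family != "smooth_additive") return(NA_real_)
  if (code %in% fit$meta$dropped) return(0)
  g <- fit$fit
  for (sm in g$smooth) {
    if (identical(sm$term, code))
      return(sum(g$edf[sm$first.para:sm$last.para]))
  }
  if (code %in% names(stats::coef(g))) return(1)   # linear fallback term
  NA_real_
}

#' Raw per-variable importance of a fitted SDM
#'
#' Smooth additive: per-term effective degrees of freedom.  Tree ensemble:
#' mean decrease in accuracy under permutation.  Maxent-like: permutation
#' importance (training AUC drop, normalized to 100).
#' @param fit an `sdm_fit`.
#' @return named numeric vector over the fit's variables (>= 0).
#' @export
sdm_importance <- function(fit) {
  switch(fit$family,
    smooth_additive = {
      v <- vapply(fit$variables, function(code) term_complexity(fit, code), 0)
      pmax(v, 0)
    },
    tree_ensemble = {
      m <- randomForest::importance(fit$fit, type = 1)
      imp <- stats::setNames(m[, 1], rownames(m))
      pmax(imp[fit$variables], 0)
    },
    maxent_like = {
      # permutation importance: drop in training AUC when one variable is
      # shuffled, normalized to sum 100 across the model's variables
      data <- fit$meta$train_data
      np <- fit$meta$n_presence; nb <- fit$meta$n_background
      sc <- predict(fit, data)
      base_auc <- auc(sc[seq_len(np)], sc[np + seq_len(nb)])
      drops <- vapply(seq_along(fit$variables), function(i) {
        set.seed(fit$meta$seed + i)
        perm <- data
        perm[[fit$variables[i]]] <- sample(perm[[fit$variables[i]]])
        s <- predict(fit, perm)
        max(0, base_auc - auc(s[seq_len(np)], s[np + seq_len(nb)]))
      }, 0)
      names(drops) <- fit$variables
      if (sum(drops) > 0) 100 * drops / sum(drops)
      else stats::setNames(rep(100 / length(drops), length(drops)), fit$variables)
    })
}
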