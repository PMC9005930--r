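# Discrimination / calibration metrics (AUC, TSS, continuous Boyce index,
# AICc) and the cross-validation harness.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic
#' `(wins + 0.5 * ties) / (n_pos * n_neg)` via midranks.
#' @param pos_scores scores at presences.
#' @param neg_scores scores at absences/background.
#' @export
auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (!np || !nn) stopf("both score lists must be non-empty")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Sensitivity, specificity and TSS at a threshold
#'
#' Scores at or above the threshold are classified as presence.
#' @param labels 0/1 vector.
#' @param scores numeric scores.
#' @param threshold classification threshold in \[0, 1\].
#' @return list with sensitivity, specificity, tss, threshold.
#' @export
tss_at <- function(labels, scores, threshold) {
  if (threshold < 0 || threshold > 1) stopf("threshold must be in [0, 1]")
  if (!any(labels == 1) || !any(labels == 0)) stopf("both classes required")
  pred <- scores >= threshold
  sens <- sum(pred & labels == 1) / sum(labels == 1)
  spec <- sum(!pred & labels == 0) / sum(labels == 0)
  list(sensitivity = sens, specificity = spec, tss = sens + spec - 1,
       threshold = threshold)
}

#' Threshold maximizing sensitivity + specificity
#'
#' Exhaustive scan over midpoints between adjacent sorted unique scores,
#' plus 0 and 1; returns the smallest maximizing threshold.
#' @inheritParams tss_at
#' @return list with threshold and tss (plus sensitivity, specificity).
#' @export
max_sss_threshold <- function(labels, scores) {
  u <- sort(unique(scores))
  cand <- sort(unique(c(0, 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
  cand <- cand[cand >= 0 & cand <= 1]
  best <- NULL
  for (t in cand) {
    m <- tss_at(labels, scores, t)
    if (is.null(best) || m$tss > best$tss + 1e-12) best <- m
  }
  best
}

#' Continuous Boyce index
#'
#' Moving windows across \[0, 1\] (default 101 windows of width 0.1); for
#' each window the predicted-to-expected ratio P/E is the fraction of
#' presence suitabilities in the window divided by the fraction of
#' background suitabilities in it (windows with zero background are
#' skipped).  The index is the Spearman rank correlation between window
#' midpoint and P/E.  With `n_windows` non-overlapping bins (width
#' `1/n_windows`) this reduces to the classical binned Boyce index;
#' `mode = "quantile"` uses rank-based background-quantile bins instead.
#'
#' @param presence_suitability suitabilities at presences, in \[0, 1\].
#' @param background_suitability suitabilities at background points.
#' @param n_windows number of windows.
#' @param window_width window width on the suitability axis.
#' @param mode `"moving"` (default) or `"quantile"`.
#' @export
boyce_index <- function(presence_suitability, background_suitability,
                        n_windows = 101, window_width = 0.1,
                        mode = c("moving", "quantile")) {
  mode <- match.arg(mode)
  if (!length(background_suitability)) stopf("background must be non-empty")
  if (mode == "quantile") {
    br <- unique(stats::quantile(background_suitability,
                                 probs = seq(0, 1, length.out = n_windows + 1), names = FALSE))
    lo <- br[-length(br)]; hi <- br[-1]
  } else {
    starts <- seq(0, 1 - window_width, length.out = n_windows)
    lo <- starts; hi <- starts + window_width
  }
  mid <- (lo + hi) / 2
  np <- length(presence_suitability); nb <- length(background_suitability)
  pe <- rep(NA_real_, length(lo))
  for (i in seq_along(lo)) {
    # last window closed on the right so suitability 1 is counted
    inw <- function(x) x >= lo[i] & (x < hi[i] | (i == length(lo) & x <= hi[i]))
    e <- sum(inw(background_suitability)) / nb
    if (e == 0) next
    pe[i] <- (sum(inw(presence_suitability)) / np) / e
  }
  ok <- !is.na(pe)
  if (sum(ok) < 3) stopf("fewer than 3 usable windows")
  suppressWarnings(stats::cor(mid[ok], pe[ok], method = "spearman"))
}

#' Small-sample corrected AIC of a fitted SDM
#'
#' For the maxent-like family the log likelihood is the sum over presences
#' of the log of the raw output normalized over the training background,
#' with K = the number of nonzero coefficients (Warren-Seifert approach);
#' for the smooth additive family the binomial deviance-based AIC with the
#' total effective degrees of freedom as K.  The tree ensemble has no
#' likelihood and returns `NA`.  When `n <= K + 1` the correction is
#' undefined and `Inf` is returned (excluded from ranking).
#'
#' @param fit an `sdm_fit`.
#' @param presence,background covariate data frames (used for the
#'   maxent-like likelihood; `presence` defines n).
#' @export
aicc <- function(fit, presence = NULL, background = NULL) {
  if (fit$family == "tree_ensemble") return(NA_real_)
  if (fit$family == "maxent_like") {
    if (is.null(presence)) stopf("presence data required for maxent-like AICc")
    raw <- predict(fit, presence, type = "raw")
    lnL <- sum(log(pmax(raw, 1e-300)))
    K <- parameter_count(fit)
    n <- nrow(presence)
  } else {
    K <- parameter_count(fit)
    lnL <- -fit$fit$deviance / 2
    n <- fit$meta$n_presence + fit$meta$n_background
  }
  if (K < 1) K <- 1
  if (n <= K + 1) return(Inf)
  2 * K - 2 * lnL + 2 * K * (K + 1) / (n - K - 1)
}

#' Cross-validate one model specification
#'
#' Each run draws a fresh spatially thinned presence set and fresh
#' pseudo-absences (seeded as `seed + run`), withholds a stratified random
#' `holdout` fraction of presences and absences, fits on the remainder and
#' evaluates on the holdout: AUC, TSS at the run's max-SSS threshold, the
#' continuous Boyce index against the run's background, and AICc on the
#' training fit.  Runs whose holdout lacks a class are redrawn (bounded
#' retries).
#'
#' @param variables covariate codes of the model spec.
#' @param family algorithm family.
#' @param stack a [covariate_stack()].
#' @param presence_cells rasterized presence cell indices (pre-thinning).
#' @param n_runs number of cross-validation runs (default 50).
#' @param holdout holdout fraction (default 0.2).
#' @param seed integer master seed for this spec.
#' @param config [pipeline_config()]-style list (thinning block, absence
#'   counts, learner control).
#' @param keep_fits retain per-run fitted models (memory-heavy).
#' @param keep_predictions retain per-run predictions over all valid stack
#'   cells (needed for ensemble layers).
#' @return list with `runs` (per-run metric data frame), `mean` (named
#'   means), and optionally `fits`, `predictions`.
#' @export
cross_validate <- function(variables, family, stack, presence_cells,
                           n_runs = 50, holdout = 0.2, seed = 1,
                           config = pipeline_config(), keep_fits = FALSE,
                           keep_predictions = FALSE) {
  grid <- stack$grid
  vcells <- valid_cells(stack)
  cell_data <- stack_values(stack, vcells, variables)
  rowof <- integer(max(vcells)); rowof[vcells] <- seq_along(vcells)
  runs <- vector("list", n_runs)
  fits <- if (keep_fits) vector("list", n_runs)
  preds <- if (keep_predictions) matrix(NA_real_, length(vcells), n_runs)
  for (r in seq_len(n_runs)) {
    pres <- thin_presences(presence_cells, grid, config$block_km,
                           config$max_per_block, seed = fanout_seed(seed, "thin", r))
    abs_cells <- sample_pseudo_absences(stack, pres, family,
                                        n_override = config$n_absences[[family]],
                                        seed = fanout_seed(seed, "abs", r))
    pdat <- cell_data[rowof[pres], , drop = FALSE]
    adat <- cell_data[rowof[abs_cells], , drop = FALSE]
    for (try in 1:5) {
      set.seed(fanout_seed(seed, "split", r, try))
      pi_h <- sample(nrow(pdat), max(1, round(holdout * nrow(pdat))))
      ai_h <- sample(nrow(adat), max(1, round(holdout * nrow(adat))))
      if (length(pi_h) < nrow(pdat) && length(ai_h) < nrow(adat)) break
      if (try == 5) stopf("cannot form a two-class holdout split")
    }
    fit <- fit_sdm(variables, pdat[-pi_h, , drop = FALSE], adat[-ai_h, , drop = FALSE],
                   family, seed = fanout_seed(seed, "fit", r), control = config$control)
    sc_p <- predict(fit, pdat[pi_h, , drop = FALSE])
    sc_a <- predict(fit, adat[ai_h, , drop = FALSE])
    lab <- c(rep(1L, length(sc_p)), rep(0L, length(sc_a)))
    sc <- c(sc_p, sc_a)
    mx <- max_sss_threshold(lab, sc)
    by <- tryCatch(boyce_index(sc_p, predict(fit, adat)), error = function(e) NA_real_)
    runs[[r]] <- data.frame(run = r, auc = auc(sc_p, sc_a), tss = mx$tss,
                            sensitivity = mx$sensitivity, specificity = mx$specificity,
                            threshold = mx$threshold, boyce = by,
                            aicc = aicc(fit, pdat[-pi_h, , drop = FALSE],
                                        adat[-ai_h, , drop = FALSE]))
    if (keep_fits) fits[[r]] <- fit
    if (keep_predictions) preds[, r] <- predict(fit, cell_data)
  }
  runs <- do.call(rbind, runs)
  means <- colMeans(runs[c("auc", "tss", "sensitivity", "specificity",
                           "threshold", "boyce")], na.rm = TRUE)
  means["aicc"] <- if (all(!is.finite(runs$aicc))) NA_real_ else
    mean(runs$aicc[is.finite(runs$aicc)])
  out <- list(runs = runs, mean = means)
  if (keep_fits) out$fits <- fits
  if (keep_predictions) out$predictions <- preds
  out
}
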