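# Candidate selection, TSS-weighted per-family ensembles, standard-error
# layers, overall ensemble, relative importance, and model-averaged
# response curves.

#' Select candidate models for one algorithm family
#'
#' Filters evaluated specs to those with mean Boyce > 0, mean AUC > 0.5
#' and mean TSS > 0 (so TSS weights are well defined), ranks by mean TSS
#' (descending), breaks near-ties (`|dTSS| < 0.01`)
#' by lower mean AICc where a likelihood is available, and keeps the top
#' `n_keep`.  Weights are proportional to mean TSS and sum to 1.  If no
#' spec passes the filters the single best-TSS spec is kept with a warning.
#'
#' @param evaluated data frame with columns spec_id, tss, auc, boyce, aicc
#'   (one row per evaluated spec).
#' @param n_keep number of candidates to keep (default 10).
#' @return list with `candidates` (data frame, ranked) and `weights`.
#' @export
select_candidates <- function(evaluated, n_keep = 10) {
  if (!nrow(evaluated)) stopf("no evaluated specs")
  pass <- evaluated[!is.na(evaluated$boyce) & evaluated$boyce > 0 &
                    evaluated$auc > 0.5 & evaluated$tss > 0, , drop = FALSE]
  if (!nrow(pass)) {
    warnf("no spec passed the Boyce/AUC filters; keeping the best-TSS spec")
    pass <- evaluated[which.max(evaluated$tss), , drop = FALSE]
  }
  ord <- order(-pass$tss)
  pass <- pass[ord, , drop = FALSE]
  # AICc tie-break within clusters of near-equal TSS
  i <- 1
  while (i <= nrow(pass)) {
    j <- i
    while (j < nrow(pass) && abs(pass$tss[j + 1] - pass$tss[i]) < 0.01) j <- j + 1
    if (j > i && any(is.finite(pass$aicc[i:j]))) {
      blk <- pass[i:j, , drop = FALSE]
      pass[i:j, ] <- blk[order(ifelse(is.finite(blk$aicc), blk$aicc, Inf)), , drop = FALSE]
    }
    i <- j + 1
  }
  kept <- utils::head(pass, n_keep)
  w <- pmax(kept$tss, 0)
  if (sum(w) == 0) w <- rep(1, nrow(kept))
  list(candidates = kept, weights = w / sum(w))
}

#' TSS-weighted family ensemble of candidate prediction layers
#'
#' Cellwise weighted mean of the candidate probability rasters.  Each
#' candidate raster should itself be the mean over that candidate's
#' cross-validation-run fits.
#'
#' @param candidate_rasters list of probability matrices on a shared grid.
#' @param weights non-negative weights summing to 1.
#' @return probability matrix (convex combination of the candidates).
#' @export
predict_family_ensemble <- function(candidate_rasters, weights) {
  if (length(candidate_rasters) != length(weights)) stopf("one weight per candidate")
  if (abs(sum(weights) - 1) > 1e-9) stopf("weights must sum to 1")
  out <- candidate_rasters[[1]] * weights[1]
  for (i in seq_along(candidate_rasters)[-1])
    out <- out + candidate_rasters[[i]] * weights[i]
  out
}

#' Standard-error layer across candidate models
#'
#' Cellwise sample standard deviation across all candidate prediction
#' layers, divided by the square root of the number of candidates
#' (`mode = "sd"` returns the plain standard deviation).  A single
#' candidate yields a zero layer with a warning.
#'
#' @param candidate_rasters list of probability matrices.
#' @param mode `"se"` (default) or `"sd"`.
#' @export
se_layer <- function(candidate_rasters, mode = c("se", "sd")) {
  mode <- match.arg(mode)
  m <- length(candidate_rasters)
  if (m < 2) {
    warnf("fewer than 2 candidates; standard-error layer is zero")
    out <- candidate_rasters[[1]] * 0
    return(out)
  }
  mu <- Reduce(`+`, candidate_rasters) / m
  ss <- Reduce(`+`, lapply(candidate_rasters, function(x) (x - mu)^2))
  sd <- sqrt(ss / (m - 1))
  if (mode == "se") sd / sqrt(m) else sd
}

#' Overall ensemble across algorithm families
#'
#' Unweighted cellwise mean of the per-family ensemble rasters.
#' @param family_rasters list of probability matrices on a shared grid.
#' @export
overall_ensemble <- function(family_rasters) {
  dims <- vapply(family_rasters, function(x) paste(dim(x), collapse = "x"), "")
  if (length(unique(dims)) != 1) stopf("grid mismatch among family rasters")
  Reduce(`+`, family_rasters) / length(family_rasters)
}

#' Combine per-family importances into one relative-importance row
#'
#' Per family, raw per-variable importances (permutation importance for the
#' maxent-like family, mean decrease in accuracy for the tree ensemble,
#' mean effective degrees of freedom for the smooth additive family) are
#' averaged across the candidates in which each code appears (codes absent
#' from all candidates score 0), normalized to sum 100 within the family,
#' averaged across families, and renormalized to sum 100.
#'
#' @param family_importances named list (per family) of named lists (per
#'   candidate) of raw importance vectors.
#' @param codes all covariate codes eligible for the species.
#' @return named numeric vector over `codes`, summing to 100.
#' @export
relative_importance <- function(family_importances, codes) {
  fam_rows <- lapply(family_importances, function(cands) {
    acc <- stats::setNames(numeric(length(codes)), codes)
    cnt <- stats::setNames(numeric(length(codes)), codes)
    for (imp in cands) {
      for (v in names(imp)) { acc[v] <- acc[v] + imp[[v]]; cnt[v] <- cnt[v] + 1 }
    }
    avg <- ifelse(cnt > 0, acc / pmax(cnt, 1), 0)
    if (sum(avg) <= 0) stopf("all-zero importances in a family")
    100 * avg / sum(avg)
  })
  out <- Reduce(`+`, fam_rows) / length(fam_rows)
  100 * out / sum(out)
}

#' Model-averaged response curves
#'
#' For each requested code and family, each candidate containing the code
#' is evaluated on an `n_grid` sweep of that code over its observed range.
#' For the smooth additive and maxent-like families the other covariates
#' are fixed at the candidate's training means; for the tree ensemble a
#' data-averaged partial-dependence sweep is used.  Per-candidate curves
#' are averaged (candidate weights renormalized among candidates containing
#' the code) within family, and the pooled curve is the mean of the family
#' curves.
#'
#' @param family_fits named list (per family) of lists of representative
#'   `sdm_fit` objects, one per candidate (aligned with `family_weights`).
#' @param family_weights named list of candidate weight vectors.
#' @param codes codes to sweep (e.g. the top-9 by relative importance).
#' @param stack a [covariate_stack()] supplying observed ranges.
#' @param n_grid sweep resolution.
#' @param pd_sample rows of training data used for tree partial dependence.
#' @return list per code: `grid`, per-family curves, `pooled`.
#' @export
response_curves <- function(family_fits, family_weights, codes, stack,
                            n_grid = 100, pd_sample = 200) {
  vals <- stack_values(stack)
  out <- list()
  for (code in codes) {
    rng <- range(vals[[code]])
    g <- seq(rng[1], rng[2], length.out = n_grid)
    fam_curves <- list()
    for (fam in names(family_fits)) {
      fits <- family_fits[[fam]]
      wts <- family_weights[[fam]]
      have <- vapply(fits, function(f) code %in% f$variables, TRUE)
      if (!any(have)) next
      w <- wts[have]; w <- w / sum(w)
      curves <- mapply(function(f, wi) {
        cv <- if (f$family == "tree_ensemble") {
          base <- f$meta$train_data
          if (nrow(base) > pd_sample) base <- base[seq(1, nrow(base), length.out = pd_sample), , drop = FALSE]
          sapply(g, function(val) { base[[code]] <- val; mean(predict(f, base)) })
        } else {
          nd <- as.data.frame(as.list(f$meta$train_means))[rep(1, n_grid), , drop = FALSE]
          nd[[code]] <- g
          predict(f, nd)
        }
        cv * wi
      }, fits[have], w, SIMPLIFY = FALSE)
      fam_curves[[fam]] <- Reduce(`+`, curves)
    }
    if (!length(fam_curves)) stopf("code '%s' absent from every candidate", code)
    out[[code]] <- list(grid = g, family = fam_curves,
                        pooled = Reduce(`+`, fam_curves) / length(fam_curves))
  }
  out
}
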