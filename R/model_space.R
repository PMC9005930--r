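# Candidate model-space enumeration: all variable subsets of size <= 6
# with no pair of correlated covariates (|r| > 0.7), plus the
# lifespan-eligibility rule for the NDVI amplitude/maximum pair.

#' Enumerate candidate variable subsets
#'
#' Returns every non-empty subset of the covariate codes with at most
#' `max_terms` members and containing no pair whose absolute Pearson
#' correlation exceeds `r_cut`.  Order is deterministic: subsets by
#' increasing size, then lexicographic in the order of `codes`.
#'
#' @param codes covariate codes.
#' @param corr correlation matrix with dimnames matching `codes`; `NA`
#'   entries (undefined correlations) do not forbid a pair.
#' @param max_terms maximum number of terms per model (default 6).
#' @param r_cut correlation cutoff in (0, 1]; pairs with `|r| > r_cut` are
#'   forbidden (default 0.7).
#' @return list of character vectors, named by spec id.
#' @export
enumerate_models <- function(codes, corr, max_terms = 6, r_cut = 0.7) {
  if (r_cut <= 0 || r_cut > 1) stopf("r_cut must be in (0, 1]")
  if (!all(codes %in% rownames(corr)))
    stopf("correlation matrix is inconsistent with codes")
  k <- length(codes)
  forbidden <- matrix(FALSE, k, k)
  sub <- abs(corr[codes, codes, drop = FALSE])
  forbidden[!is.na(sub) & sub > r_cut] <- TRUE
  diag(forbidden) <- FALSE
  specs <- list()
  for (size in seq_len(min(max_terms, k))) {
    idx <- utils::combn(k, size, simplify = FALSE)
    for (ii in idx) {
      if (size > 1) {
        pairs <- utils::combn(ii, 2)
        if (any(forbidden[t(pairs)])) next
      }
      specs[[length(specs) + 1L]] <- codes[ii]
    }
  }
  names(specs) <- sprintf("m%05d", seq_along(specs))
  specs
}

#' Filter model specs by species lifespan
#'
#' The NDVI amplitude (AMP) covariate represents vegetation green-up and
#' is eligible only for annual species; the NDVI maximum (MAXN) represents
#' canopy photosynthetic activity and is eligible only for perennials.
#' Drops every spec containing the ineligible code.
#'
#' @param specs list of character vectors from [enumerate_models()].
#' @param lifespan `"annual"` or `"perennial"`.
#' @return filtered spec list (names preserved).
#' @export
lifespan_filter <- function(specs, lifespan = c("annual", "perennial")) {
  lifespan <- match.arg(lifespan)
  banned <- if (lifespan == "annual") "MAXN" else "AMP"
  specs[!vapply(specs, function(v) banned %in% v, logical(1))]
}

#' Seeded random cap on the model space
#'
#' Full enumeration is cluster-scale for 14 covariates; for desk-scale runs
#' a seeded uniform subsample of the specs keeps the pipeline tractable.
#'
#' @param specs spec list.
#' @param cap maximum number of specs to keep (`Inf` = no cap).
#' @param seed integer seed.
#' @return subsampled spec list in original order.
#' @export
cap_specs <- function(specs, cap = Inf, seed = 1) {
  if (!is.finite(cap) || length(specs) <= cap) return(specs)
  set.seed(seed)
  keep <- sort(sample(length(specs), cap))
  specs[keep]
}

#' Export a spec list as a data frame
#' @param specs spec list.
#' @export
specs_as_df <- function(specs) {
  data.frame(spec_id = names(specs),
             variables = vapply(specs, paste, "", collapse = "+"),
             n_terms = lengths(specs),
             row.names = NULL, stringsAsFactors = FALSE)
}
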