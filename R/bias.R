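# Systematic sampling-bias diagnostic: aggregate per-species habitat and
# uncertainty layers, compute distance to developed features, and regress
# the aggregates on distance with a flexible smooth.

#' Aggregate habitat-probability and standard-error layers across species
#'
#' Cellwise unweighted means of the overall probability rasters and SE
#' rasters of a set of per-species results.
#'
#' @param results list of `sdm_result` objects (or a list of lists with
#'   elements `overall` and `se`).
#' @return list with `prob` and `se` matrices.
#' @export
aggregate_layers <- function(results) {
  if (!length(results)) stopf("need >= 1 species")
  probs <- lapply(results, `[[`, "overall")
  ses <- lapply(results, `[[`, "se")
  dims <- vapply(probs, function(x) paste(dim(x), collapse = "x"), "")
  if (length(unique(dims)) != 1) stopf("grid mismatch among species layers")
  list(prob = Reduce(`+`, probs) / length(probs),
       se = Reduce(`+`, ses) / length(ses))
}

#' Euclidean distance to the nearest feature cell
#'
#' Exact two-pass squared distance transform over cell centres: distances
#' are computed column-wise to the nearest feature row, then minimised
#' across columns.  Feature cells have distance 0.
#'
#' @param feature_mask logical matrix, `TRUE` on developed-feature cells.
#' @param cell_km cell size in km.
#' @return matrix of distances in km.
#' @export
distance_to_features <- function(feature_mask, cell_km = 1) {
  if (!any(feature_mask)) stopf("feature mask is empty")
  nr <- nrow(feature_mask); nc <- ncol(feature_mask)
  # pass 1: per column, distance (in rows) to nearest feature in that column
  g <- matrix(Inf, nr, nc)
  for (j in seq_len(nc)) {
    rows <- which(feature_mask[, j])
    if (!length(rows)) next
    d <- rep(Inf, nr); d[rows] <- 0
    for (i in 2:nr) d[i] <- min(d[i], d[i - 1] + 1)
    for (i in (nr - 1):1) d[i] <- min(d[i], d[i + 1] + 1)
    g[, j] <- d
  }
  # pass 2: per row, minimise g^2 + column offset^2 across columns
  out <- matrix(Inf, nr, nc)
  g2 <- g^2
  for (j in seq_len(nc)) {
    off2 <- (seq_len(nc) - j)^2
    cand <- sweep(g2, 2, off2, `+`)     # nr x nc: candidate squared dists
    out[, j] <- apply(cand, 1, min)
  }
  sqrt(out) * cell_km
}

#' Regress an aggregated layer on distance to development
#'
#' Fits a univariate penalized thin-plate smooth (about 10 basis
#' functions) of the aggregated value on distance over all valid cells and
#' reports the coefficient of determination `R^2 = 1 - SSE/SST`, plus an
#' 8-equal-width-bin summary of the distance range (per-bin n, mean,
#' quartiles) for violin-style display.
#'
#' @param aggregated matrix of aggregated probabilities or SEs.
#' @param distance matrix of distances (km) on the same grid.
#' @param k smooth basis size.
#' @param n_bins number of equal-width distance bins (default 8).
#' @return list of class `bias_report`: `r2`, `bins`, `n_cells`.
#' @export
bias_regression <- function(aggregated, distance, k = 10, n_bins = 8) {
  ok <- is.finite(aggregated) & is.finite(distance)
  y <- aggregated[ok]; x <- distance[ok]
  if (length(y) < 50) stopf("need >= 50 valid cells")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    r2 <- NA_real_
  } else {
    fit <- mgcv::gam(y ~ s(x, k = k), method = "REML")
    r2 <- 1 - sum(stats::residuals(fit)^2) / sst
  }
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- cut(x, breaks, include.lowest = TRUE)
  qs <- tapply(y, bin, function(v) stats::quantile(v, c(0.25, 0.5, 0.75)))
  bins <- data.frame(bin = levels(bin),
                     lower = breaks[-length(breaks)], upper = breaks[-1],
                     n = as.integer(table(bin)),
                     mean = as.numeric(tapply(y, bin, mean)),
                     q25 = vapply(qs, function(q) if (is.null(q)) NA_real_ else q[[1]], 0),
                     median = vapply(qs, function(q) if (is.null(q)) NA_real_ else q[[2]], 0),
                     q75 = vapply(qs, function(q) if (is.null(q)) NA_real_ else q[[3]], 0),
                     row.names = NULL)
  structure(list(r2 = r2, bins = bins, n_cells = length(y)),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("<bias_report> R^2 = %.4f over %d cells, %d distance bins\n",
              x$r2, x$n_cells, nrow(x$bins)))
  invisible(x)
}

#' Full bias diagnostic for a set of species results
#'
#' Aggregates the species layers, computes distance to the supplied
#' feature mask, and regresses both aggregates on distance.
#'
#' @param results list of `sdm_result` objects.
#' @param feature_mask logical matrix of developed-feature cells.
#' @param cell_km cell size in km.
#' @return list with `r2_prob`, `r2_se`, the two `bias_report`s and the
#'   distance raster.
#' @export
bias_diagnostic <- function(results, feature_mask, cell_km = 1) {
  agg <- aggregate_layers(results)
  dist <- distance_to_features(feature_mask, cell_km)
  rp <- bias_regression(agg$prob, dist)
  rs <- bias_regression(agg$se, dist)
  list(r2_prob = rp$r2, r2_se = rs$r2, prob_report = rp, se_report = rs,
       distance = dist, aggregated = agg)
}
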