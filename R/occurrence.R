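# Occurrence QC, rasterization to presence cells, grid-block spatial
# thinning, and pseudo-absence sampling per algorithm family.

#' Quality-control filter for occurrence records
#'
#' Removes records with positional uncertainty above the threshold (records
#' with missing uncertainty are kept), records falling outside the grid or
#' on masked cells, and records on water cells when a water mask is given.
#' The counts removed by each rule are attached as attribute `qc_report`.
#'
#' @param occ occurrence data frame with columns x, y and optionally
#'   uncertainty_km.
#' @param stack a [covariate_stack()].
#' @param max_uncertainty_km positional-uncertainty threshold in km
#'   (default 1, the modelling resolution).
#' @param water_mask optional logical matrix, `TRUE` on water cells.
#' @return filtered data frame with attribute `qc_report`.
#' @export
qc_filter <- function(occ, stack, max_uncertainty_km = 1, water_mask = NULL) {
  n0 <- nrow(occ)
  report <- c(uncertain = 0L, outside = 0L, masked = 0L, water = 0L)
  if (n0 == 0) {
    attr(occ, "qc_report") <- report
    return(occ)
  }
  unc <- if ("uncertainty_km" %in% names(occ)) occ$uncertainty_km else rep(NA_real_, n0)
  drop_unc <- !is.na(unc) & unc > max_uncertainty_km
  cells <- xy_cell(stack$grid, occ$x, occ$y)
  drop_out <- is.na(cells)
  drop_mask <- !drop_out & !stack$mask[cells]
  drop_water <- rep(FALSE, n0)
  if (!is.null(water_mask))
    drop_water <- !drop_out & water_mask[ifelse(drop_out, 1L, cells)]
  report["uncertain"] <- sum(drop_unc)
  report["outside"] <- sum(drop_out & !drop_unc)
  report["masked"] <- sum(drop_mask & !drop_unc & !drop_out)
  report["water"] <- sum(drop_water & !drop_unc & !drop_out & !drop_mask)
  keep <- !(drop_unc | drop_out | drop_mask | drop_water)
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_report") <- report
  out
}

#' Rasterize occurrences to unique presence cells
#'
#' @param occ occurrence data frame with x, y columns.
#' @param grid a [grid_spec()].
#' @return sorted vector of unique linear cell indices (records outside the
#'   grid are ignored).
#' @export
rasterize_presences <- function(occ, grid) {
  if (!nrow(occ)) return(integer(0))
  cells <- xy_cell(grid, occ$x, occ$y)
  sort(unique(cells[!is.na(cells)]))
}

#' Spatially thin presence cells by grid blocks
#'
#' Partitions the grid into `block_km x block_km` blocks anchored at the
#' grid origin and retains at most `max_per_block` presence cells per
#' block, chosen uniformly at random.  Deterministic under `seed`.
#'
#' @param cells presence cell indices.
#' @param grid a [grid_spec()].
#' @param block_km block edge length in km (>= cell size); default 10.
#' @param max_per_block maximum cells retained per block; default 3.
#' @param seed integer seed.
#' @return sorted vector of retained cell indices.
#' @export
thin_presences <- function(cells, grid, block_km = 10, max_per_block = 3, seed = 1) {
  if (block_km < grid$cell_km) stopf("block_km must be >= cell_km")
  if (!length(cells)) return(integer(0))
  row <- (cells - 1L) %% grid$nrows + 1L
  col <- (cells - 1L) %/% grid$nrows + 1L
  cpb <- block_km / grid$cell_km   # cells per block edge
  # blocks anchored at the origin corner (row nrows, col 1 is the SW cell)
  block_r <- floor((grid$nrows - row) / cpb)
  block_c <- floor((col - 1) / cpb)
  key <- paste(block_r, block_c)
  set.seed(seed)
  kept <- unlist(lapply(split(cells, key), function(cc) {
    if (length(cc) <= max_per_block) cc else sample(cc, max_per_block)
  }), use.names = FALSE)
  sort(kept)
}

#' Pseudo-absence / background sampling per algorithm family
#'
#' Draws uniform random cells without replacement from the valid cells of
#' the stack.  Defaults follow common large-sample recommendations for
#' presence-background modelling: 10,000 for the smooth additive and
#' maximum-entropy families (for the latter these are background points and
#' presence cells are *not* excluded), and as many absences as presences
#' for the tree ensemble.  Requests above the number of available cells are
#' capped with a warning.
#'
#' @param stack a [covariate_stack()].
#' @param presence_cells presence cell indices.
#' @param algorithm_family one of `"smooth_additive"`, `"tree_ensemble"`,
#'   `"maxent_like"`.
#' @param n_override absolute count overriding the family default.
#' @param exclude_presence exclude presence cells from the draw; forced to
#'   `FALSE` for `maxent_like` unless overridden explicitly.
#' @param seed integer seed.
#' @return vector of absence/background cell indices.
#' @export
sample_pseudo_absences <- function(stack, presence_cells,
                                   algorithm_family = c("smooth_additive", "tree_ensemble", "maxent_like"),
                                   n_override = NULL, exclude_presence = NULL, seed = 1) {
  algorithm_family <- match.arg(algorithm_family)
  n <- n_override %||% switch(algorithm_family,
    smooth_additive = 10000L,
    maxent_like = 10000L,
    tree_ensemble = length(presence_cells))
  if (is.null(exclude_presence))
    exclude_presence <- algorithm_family != "maxent_like"
  pool <- valid_cells(stack)
  if (exclude_presence) pool <- setdiff(pool, presence_cells)
  if (!length(pool)) stopf("no candidate cells available for pseudo-absences")
  if (n > length(pool)) {
    warnf("requested %d pseudo-absences but only %d candidate cells; capping", n, length(pool))
    n <- length(pool)
  }
  set.seed(seed)
  sort(sample(pool, n))
}
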