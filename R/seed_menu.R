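# Decision-support engine: stack per-species habitat rasters, extract
# probabilities at restoration sites, apply suitability thresholds
# (inclusive >=, AND across sites), join trait attributes, and count
# per-cell species coverage.

#' Build a site set from coordinates or polygons
#'
#' Points come as a data frame with columns site_id, x, y.  Polygons come
#' as a named list of single-ring vertex matrices (two columns, x and y, in
#' km); multipart polygons (lists of rings) are rejected.
#'
#' @param coords optional point data frame.
#' @param polygons optional named list of vertex matrices.
#' @param grid a [grid_spec()]; geometries must fall inside its bounding
#'   box.
#' @return object of class `site_set`.
#' @export
site_set <- function(coords = NULL, polygons = NULL, grid = NULL) {
  sites <- list()
  if (!is.null(coords)) {
    if (!all(c("site_id", "x", "y") %in% names(coords)))
      stopf("coords needs columns site_id, x, y")
    for (i in seq_len(nrow(coords)))
      sites[[as.character(coords$site_id[i])]] <-
        list(type = "point", x = coords$x[i], y = coords$y[i])
  }
  if (!is.null(polygons)) {
    if (is.null(names(polygons))) stopf("polygons must be a named list")
    for (id in names(polygons)) {
      p <- polygons[[id]]
      if (is.list(p) && !is.data.frame(p))
        stopf("site '%s' is a multipart polygon; supply one ring per site", id)
      p <- as.matrix(p)
      if (ncol(p) != 2 || nrow(p) < 3) stopf("polygon '%s' needs >= 3 x,y vertices", id)
      sites[[id]] <- list(type = "polygon", vertices = p)
    }
  }
  if (!length(sites)) stopf("no sites supplied")
  if (!is.null(grid)) {
    xmax <- grid$origin_x + grid$ncols * grid$cell_km
    ymax <- grid$origin_y + grid$nrows * grid$cell_km
    for (id in names(sites)) {
      s <- sites[[id]]
      xs <- if (s$type == "point") s$x else s$vertices[, 1]
      ys <- if (s$type == "point") s$y else s$vertices[, 2]
      if (any(xs < grid$origin_x | xs > xmax | ys < grid$origin_y | ys > ymax))
        stopf("site '%s' falls outside the grid", id)
    }
  }
  structure(sites, class = "site_set")
}

#' Read a site set from a CSV of coordinates
#' @param path CSV with columns site_id, x, y.
#' @param grid optional [grid_spec()] for bounds checking.
#' @export
read_sites_csv <- function(path, grid = NULL) {
  site_set(coords = utils::read.csv(path, stringsAsFactors = FALSE), grid = grid)
}

# ray-casting point-in-polygon (boundary-inclusive up to FP tolerance)
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside <- !inside
    j <- i
  }
  inside
}

#' Extract species habitat probabilities at sites
#'
#' Points take the value of their containing cell; polygons summarise the
#' valid cells whose centres fall inside the ring with `polygon_rule`.
#' Sites covering no valid cell raise an error.
#'
#' @param species_rasters named list of probability matrices (one per
#'   species) on the shared grid.
#' @param grid the [grid_spec()] of the rasters.
#' @param sites a [site_set()].
#' @param polygon_rule `"mean"` (default), `"min"` or `"max"`.
#' @return data frame: species x sites probability table (rownames =
#'   species ids), with attribute `site_ids`.
#' @export
extract_at_sites <- function(species_rasters, grid, sites,
                             polygon_rule = c("mean", "min", "max")) {
  polygon_rule <- match.arg(polygon_rule)
  agg <- switch(polygon_rule, mean = mean, min = min, max = max)
  cell_lists <- lapply(names(sites), function(id) {
    s <- sites[[id]]
    if (s$type == "point") {
      cell <- xy_cell(grid, s$x, s$y)
      if (is.na(cell)) stopf("site '%s' is outside the grid", id)
      cell
    } else {
      allc <- seq_len(grid$nrows * grid$ncols)
      xy <- cell_xy(grid, allc)
      inb <- xy[, 1] >= min(s$vertices[, 1]) & xy[, 1] <= max(s$vertices[, 1]) &
             xy[, 2] >= min(s$vertices[, 2]) & xy[, 2] <= max(s$vertices[, 2])
      cand <- allc[inb]
      inside <- vapply(cand, function(cc) {
        point_in_polygon(xy[cc, 1], xy[cc, 2], s$vertices[, 1], s$vertices[, 2])
      }, TRUE)
      cells <- cand[inside]
      if (!length(cells)) stopf("polygon '%s' intersects zero cells", id)
      cells
    }
  })
  names(cell_lists) <- names(sites)
  out <- sapply(names(sites), function(id) {
    vapply(species_rasters, function(r) {
      v <- r[cell_lists[[id]]]
      v <- v[is.finite(v)]
      if (!length(v)) stopf("site '%s' covers only masked cells", id)
      agg(v)
    }, 0)
  })
  out <- matrix(out, nrow = length(species_rasters),
                dimnames = list(names(species_rasters), names(sites)))
  df <- as.data.frame(out)
  attr(df, "site_ids") <- names(sites)
  df
}

#' Resolve per-species suitability thresholds
#'
#' @param rule `"fixed"`, `"max_sss"` or `"sens_eq_spec"`.
#' @param species species ids.
#' @param fixed_value threshold in \[0, 1\] when `rule = "fixed"`.
#' @param species_thresholds named vector of per-species thresholds (from
#'   the per-species `sdm_result`s) for the species-specific rules.
#' @return named threshold vector over `species`.
#' @export
threshold_rule <- function(rule = c("fixed", "max_sss", "sens_eq_spec"),
                           species, fixed_value = NULL, species_thresholds = NULL) {
  rule <- match.arg(rule)
  if (rule == "fixed") {
    if (is.null(fixed_value) || fixed_value < 0 || fixed_value > 1)
      stopf("fixed threshold must be in [0, 1]")
    return(stats::setNames(rep(fixed_value, length(species)), species))
  }
  if (is.null(species_thresholds) || !all(species %in% names(species_thresholds)))
    stopf("species-specific thresholds unresolved for: %s",
          paste(setdiff(species, names(species_thresholds)), collapse = ", "))
  out <- species_thresholds[species]
  if (any(out < 0 | out > 1)) stopf("resolved thresholds must be in [0, 1]")
  out
}

#' Apply a threshold rule to a site probability table
#'
#' A species is included iff its probability is at or above its threshold
#' at every site (inclusive comparison, AND across sites).
#'
#' @param prob_table species x sites data frame from [extract_at_sites()].
#' @param thresholds named per-species threshold vector (see
#'   [threshold_rule()]).
#' @return data frame: species_id, per-site probabilities, min_probability,
#'   threshold, included.
#' @export
apply_threshold <- function(prob_table, thresholds) {
  species <- rownames(prob_table)
  if (!all(species %in% names(thresholds)))
    stopf("unresolved threshold for: %s",
          paste(setdiff(species, names(thresholds)), collapse = ", "))
  thr <- thresholds[species]
  minp <- apply(as.matrix(prob_table), 1, min)
  data.frame(species_id = species, prob_table, min_probability = minp,
             threshold = unname(thr), included = minp >= unname(thr),
             row.names = NULL, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Build a seed menu table
#'
#' One row per included species (or all species when
#' `include_all = TRUE`), joined to the selected trait columns.  Species
#' missing from the trait table keep their row with traits `NA` and a
#' warning.
#'
#' @param inclusion data frame from [apply_threshold()].
#' @param traits trait table with a species_id column.
#' @param selected_traits trait column names to join (default all).
#' @param include_all keep excluded species (flagged) instead of dropping
#'   them.
#' @return data frame of class `seed_menu` with attribute `metadata`.
#' @export
build_menu <- function(inclusion, traits, selected_traits = NULL,
                       include_all = FALSE) {
  available <- setdiff(names(traits), "species_id")
  if (is.null(selected_traits)) selected_traits <- available
  unknown <- setdiff(selected_traits, available)
  if (length(unknown))
    stopf("unknown trait(s): %s (available: %s)",
          paste(unknown, collapse = ", "), paste(available, collapse = ", "))
  rows <- if (include_all) inclusion else inclusion[inclusion$included, , drop = FALSE]
  missing <- setdiff(rows$species_id, traits$species_id)
  if (length(missing))
    warnf("species missing from trait table: %s", paste(missing, collapse = ", "))
  idx <- match(rows$species_id, traits$species_id)
  out <- cbind(rows, traits[idx, selected_traits, drop = FALSE])
  rownames(out) <- NULL
  attr(out, "metadata") <- list(selected_traits = selected_traits,
                                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                n_sites = sum(!names(inclusion) %in%
                                  c("species_id", "min_probability", "threshold", "included")))
  class(out) <- c("seed_menu", "data.frame")
  out
}

#' Write a seed menu as CSV with metadata header comments
#' @param menu a [build_menu()] result.
#' @param path file path.
#' @export
write_menu_csv <- function(menu, path) {
  md <- attr(menu, "metadata")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed menu generated %s; traits: %s", md$timestamp,
                     paste(md$selected_traits, collapse = ",")), con)
  utils::write.csv(as.data.frame(menu), con, row.names = FALSE)
  invisible(path)
}

#' Species coverage map
#'
#' Per-cell count of species whose habitat probability is at or above
#' their threshold; masked cells are `NA`.
#'
#' @param species_rasters named list of probability matrices on a shared
#'   grid.
#' @param thresholds named per-species threshold vector.
#' @return integer matrix of species counts.
#' @export
coverage_map <- function(species_rasters, thresholds) {
  if (!length(species_rasters)) stopf("need >= 1 species layer")
  dims <- vapply(species_rasters, function(x) paste(dim(x), collapse = "x"), "")
  if (length(unique(dims)) != 1) stopf("grid mismatch among species layers")
  species <- names(species_rasters)
  if (!all(species %in% names(thresholds)))
    stopf("unresolved threshold for: %s",
          paste(setdiff(species, names(thresholds)), collapse = ", "))
  counts <- Reduce(`+`, lapply(species, function(sp) {
    r <- species_rasters[[sp]]
    out <- (r >= thresholds[[sp]]) * 1
    out[!is.finite(r)] <- 0
    out
  }))
  anyvalid <- Reduce(`|`, lapply(species_rasters, is.finite))
  counts[!anyvalid] <- NA_real_
  counts
}
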