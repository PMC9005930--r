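# Grid and covariate-stack model.
#
# Rasters are plain R matrices (nrows x ncols) on a projected grid in km.
# Row 1 is the northern edge; columns run west to east; cell centres define
# cell coordinates; intervals are half-open so the index <-> coordinate
# mapping is a bijection on the grid.  Cells are addressed by their R linear
# (column-major) matrix index.

#' Covariate codes used throughout the pipeline
#'
#' The 14 environmental covariate codes recognised by the stack model:
#' summer/winter precipitation (SP, WP), summer maximum / winter minimum
#' temperature and annual temperature range (Tmax, Tmin, Trange), annual
#' heat-moisture index (AHM), climatic moisture deficit (CMD), NDVI
#' amplitude and maximum (AMP, MAXN), soil water stress (SWS), surface
#' texture (Text), heat load index (HLI), slope (Slope), and topographic
#' position index (TPI).
#' @export
covariate_codes <- function() {
  c("SP", "WP", "Tmax", "Tmin", "Trange", "AHM", "CMD",
    "AMP", "MAXN", "SWS", "Text", "HLI", "Slope", "TPI")
}

#' Define a raster grid
#'
#' @param nrows,ncols grid dimensions (>= 1).
#' @param cell_km cell edge length in km (> 0); the modelling resolution
#'   defaults to 1 km.
#' @param origin_x,origin_y projected coordinates (km) of the grid's
#'   south-west corner.
#' @param crs_tag free-text tag describing the projection.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(nrows, ncols, cell_km = 1, origin_x = 0, origin_y = 0,
                      crs_tag = "local-km") {
  if (nrows < 1 || ncols < 1) stopf("nrows and ncols must be >= 1")
  if (cell_km <= 0) stopf("cell_km must be > 0")
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 cell_km = cell_km, origin_x = origin_x, origin_y = origin_y,
                 crs_tag = crs_tag),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.3g km resolution, origin (%g, %g)\n",
              x$nrows, x$ncols, x$cell_km, x$origin_x, x$origin_y))
  invisible(x)
}

#' Cell index to centre coordinates and back
#'
#' `cell_xy()` maps linear cell indices (column-major) to cell-centre
#' coordinates; `xy_cell()` maps coordinates to the index of the containing
#' cell (`NA` outside the grid).  Cells are half-open so the two functions
#' are inverse on the grid interior.
#' @param grid a [grid_spec()].
#' @param cells integer vector of linear cell indices.
#' @return `cell_xy`: two-column matrix of x, y (km).
#' @export
cell_xy <- function(grid, cells) {
  row <- (cells - 1L) %% grid$nrows + 1L
  col <- (cells - 1L) %/% grid$nrows + 1L
  x <- grid$origin_x + (col - 0.5) * grid$cell_km
  y <- grid$origin_y + (grid$nrows - row + 0.5) * grid$cell_km
  cbind(x = x, y = y)
}

#' @rdname cell_xy
#' @param x,y coordinate vectors (km).
#' @export
xy_cell <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_km) + 1
  row <- grid$nrows - floor((y - grid$origin_y) / grid$cell_km)
  ok <- col >= 1 & col <= grid$ncols & row >= 1 & row <= grid$nrows &
    is.finite(x) & is.finite(y)
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer((col[ok] - 1) * grid$nrows + row[ok])
  out
}

#' Build a covariate stack
#'
#' A covariate stack holds named raster layers sharing one grid, plus a
#' logical validity mask (`TRUE` = usable cell).  Masked cells carry `NA`.
#'
#' @param grid a [grid_spec()].
#' @param layers named list of numeric matrices (`nrows x ncols`); names are
#'   covariate codes and must be unique.
#' @param mask optional logical matrix; defaults to cells finite in every
#'   layer.
#' @return an object of class `covariate_stack`.
#' @export
covariate_stack <- function(grid, layers, mask = NULL) {
  if (!inherits(grid, "grid_spec")) stopf("grid must be a grid_spec")
  codes <- names(layers)
  if (is.null(codes) || any(codes == "")) stopf("layers must be named")
  if (anyDuplicated(codes)) stopf("duplicate covariate codes: %s",
                                  paste(unique(codes[duplicated(codes)]), collapse = ", "))
  for (code in codes) {
    m <- layers[[code]]
    if (!is.matrix(m) || nrow(m) != grid$nrows || ncol(m) != grid$ncols)
      stopf("layer '%s' does not match the grid (%d x %d)", code, grid$nrows, grid$ncols)
    storage.mode(layers[[code]]) <- "double"
  }
  if (is.null(mask)) {
    mask <- Reduce(`&`, lapply(layers, is.finite))
    if (is.null(mask)) mask <- matrix(TRUE, grid$nrows, grid$ncols)
  }
  if (!is.logical(mask) || nrow(mask) != grid$nrows || ncol(mask) != grid$ncols)
    stopf("mask must be a logical nrows x ncols matrix")
  for (code in codes) layers[[code]][!mask] <- NA_real_
  structure(list(grid = grid, layers = layers, mask = mask),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("<covariate_stack> %d layers [%s] on %d x %d grid (%d valid cells)\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$grid$nrows, x$grid$ncols, sum(x$mask)))
  invisible(x)
}

#' @export
n_layers <- function(stack) length(stack$layers)

#' Linear indices of valid (non-masked) cells
#' @param stack a [covariate_stack()].
#' @export
valid_cells <- function(stack) which(stack$mask)

#' Extract covariate values at cells
#'
#' @param stack a [covariate_stack()].
#' @param cells linear cell indices; default all valid cells.
#' @param codes covariate codes to extract; default all.
#' @return data frame, one row per cell, one column per code.
#' @export
stack_values <- function(stack, cells = valid_cells(stack),
                         codes = names(stack$layers)) {
  missing <- setdiff(codes, names(stack$layers))
  if (length(missing)) stopf("unknown covariate code(s): %s", paste(missing, collapse = ", "))
  out <- lapply(stack$layers[codes], function(m) m[cells])
  as.data.frame(out, optional = TRUE)
}

#' Annual heat-moisture index
#'
#' `AHM = (MAT + 10) / (MAP / 1000)`, where MAT is mean annual temperature
#' (deg C) and MAP mean annual precipitation (mm).  Higher values indicate
#' hotter, drier conditions.
#' @param mat_c mean annual temperature in degrees Celsius.
#' @param map_mm mean annual precipitation in mm (> 0).
#' @export
annual_heat_moisture <- function(mat_c, map_mm) {
  if (any(map_mm <= 0)) stopf("map_mm must be > 0")
  (mat_c + 10) / (map_mm / 1000)
}

#' Pairwise Pearson correlations among stack layers
#'
#' Computed over the jointly valid cells of all layers.  A constant layer's
#' correlations are undefined and reported as `NA` (never coerced to 0);
#' the diagonal is exactly 1.
#' @param stack a [covariate_stack()].
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(stack) {
  cells <- valid_cells(stack)
  if (length(cells) < 3) stopf("need >= 3 jointly valid cells")
  vals <- as.matrix(stack_values(stack, cells))
  suppressWarnings(r <- stats::cor(vals))
  diag(r) <- 1
  r
}

#' Write / read a covariate stack
#'
#' Serialises the stack to a self-describing JSON text file at full numeric
#' precision; `read_stack(write_stack(x, f))` reproduces layer values, band
#' names, grid and mask bit-exactly.
#' @param stack a [covariate_stack()].
#' @param path file path.
#' @export
write_stack <- function(stack, path) {
  payload <- list(
    format = "seedmenus-stack",
    version = 1L,
    grid = unclass(stack$grid),
    codes = names(stack$layers),
    mask = as.integer(stack$mask),
    layers = lapply(stack$layers, function(m) {
      v <- as.vector(m)
      v[!is.finite(v)] <- NA_real_
      v
    })
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "seedmenus-stack")) stopf("not a seedmenus stack file: %s", path)
  g <- p$grid
  grid <- grid_spec(g$nrows, g$ncols, g$cell_km, g$origin_x, g$origin_y, g$crs_tag)
  if (anyDuplicated(p$codes)) stopf("duplicate band names in %s", path)
  if (!setequal(names(p$layers), p$codes)) stopf("band names missing or inconsistent in %s", path)
  mask <- matrix(as.logical(p$mask), grid$nrows, grid$ncols)
  layers <- lapply(p$layers[p$codes], function(v) {
    if (length(v) != grid$nrows * grid$ncols) stopf("grid mismatch between bands in %s", path)
    matrix(as.double(v), grid$nrows, grid$ncols)
  })
  covariate_stack(grid, layers, mask)
}

#' Export one layer as CSV
#'
#' Long-format export with columns row, col, x, y, value (valid cells only).
#' @param stack a [covariate_stack()].
#' @param code covariate code.
#' @param path file path.
#' @export
layer_to_csv <- function(stack, code, path) {
  if (!code %in% names(stack$layers)) stopf("unknown covariate code: %s", code)
  cells <- valid_cells(stack)
  xy <- cell_xy(stack$grid, cells)
  df <- data.frame(row = (cells - 1L) %% stack$grid$nrows + 1L,
                   col = (cells - 1L) %/% stack$grid$nrows + 1L,
                   x = xy[, 1], y = xy[, 2],
                   value = stack$layers[[code]][cells])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
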