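#' Define a regular longitude--latitude grid
#'
#' All gridded objects in the package (climate layers, suitability maps,
#' ecoregion labels) live on a shared `grid_spec`: a regular lon/lat raster
#' with pixel-centre registration. Row 1 is the southernmost row, column 1
#' the westernmost column; the pixel centre of cell `(r, c)` is at
#' `origin + (index - 0.5) * cell_size`.
#'
#' @param n_rows,n_cols Positive integers, grid dimensions.
#' @param cell_size Cell edge length in decimal degrees. The default `1/6`
#'   degree corresponds to the 10-arc-minute resolution commonly used for
#'   global bioclimatic layers.
#' @param origin_lon,origin_lat Decimal-degree coordinates of the grid's
#'   south-west corner (the outer edge, not the first pixel centre).
#' @param nodata_mask Optional logical matrix (`n_rows x n_cols`); `TRUE`
#'   marks pixels excluded from every sum, sample and regression.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 1 / 6,
                      origin_lon = 0, origin_lat = 0, nodata_mask = NULL) {
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L,
            n_rows >= 1, n_cols >= 1, n_rows == round(n_rows),
            n_cols == round(n_cols))
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("'cell_size' must be a single positive number")
  }
  if (!is.null(nodata_mask)) {
    stopifnot(is.logical(nodata_mask),
              identical(dim(nodata_mask), c(as.integer(n_rows), as.integer(n_cols))))
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = cell_size, origin_lon = origin_lon,
         origin_lat = origin_lat, nodata_mask = nodata_mask),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %.4f deg, origin (%.3f, %.3f)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat))
  if (!is.null(x$nodata_mask)) {
    cat(sprintf("  nodata pixels: %d\n", sum(x$nodata_mask)))
  }
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cell_size - b$cell_size) <= tol &&
    abs(a$origin_lon - b$origin_lon) <= tol &&
    abs(a$origin_lat - b$origin_lat) <= tol
}

#' Map coordinates to grid cell indices
#'
#' Cell assignment uses `floor((coord - origin) / cell_size)`, the same rule
#' the occurrence-cleaning stage uses to collapse within-cell duplicates.
#' Points outside the grid extent get `NA` indices.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Numeric vectors of equal length.
#' @return A data.frame with integer columns `row` and `col` (`NA` outside
#'   the extent).
#' @export
cell_index <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "grid_spec"), length(lon) == length(lat))
  col <- floor((lon - grid$origin_lon) / grid$cell_size) + 1
  row <- floor((lat - grid$origin_lat) / grid$cell_size) + 1
  # a point exactly on the east/north outer edge belongs to the last cell
  col[lon == grid$origin_lon + grid$n_cols * grid$cell_size] <- grid$n_cols
  row[lat == grid$origin_lat + grid$n_rows * grid$cell_size] <- grid$n_rows
  bad <- !is.finite(col) | !is.finite(row) |
    col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Pixel-centre coordinates of grid cells
#'
#' @param grid A [grid_spec()].
#' @param row,col Integer vectors of equal length.
#' @return A data.frame with numeric columns `lon` and `lat`.
#' @export
cell_center <- function(grid, row, col) {
  stopifnot(inherits(grid, "grid_spec"), length(row) == length(col))
  data.frame(lon = grid$origin_lon + (col - 0.5) * grid$cell_size,
             lat = grid$origin_lat + (row - 0.5) * grid$cell_size)
}

# latitude of the centre of every row, recycled over the full matrix layout
row_latitudes <- function(grid) {
  grid$origin_lat + (seq_len(grid$n_rows) - 0.5) * grid$cell_size
}

# logical matrix of usable pixels
usable_mask <- function(grid) {
  m <- matrix(TRUE, grid$n_rows, grid$n_cols)
  if (!is.null(grid$nodata_mask)) m[grid$nodata_mask] <- FALSE
  m
}
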