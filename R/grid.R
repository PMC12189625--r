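#' Define a regular lon/lat analysis grid
#'
#' A `grid_spec` describes a regular WGS84 lon/lat lattice by its south-west
#' corner, a square cell size in decimal degrees and its dimensions. All
#' layers, masks and block aggregates in the package are matrices indexed
#' `[row, col]` with row 1 the southernmost row and column 1 the westernmost
#' column; cell centres sit at `origin + (index - 0.5) * cellsize`.
#'
#' Cell membership is half-open: a cell covers
#' `[west, west + cellsize) x [south, south + cellsize)`, except that the
#' northern and eastern outer boundaries of the grid are closed so a point on
#' the outer edge still maps to exactly one cell.
#'
#' @param xmin,ymin western / southern edge of the grid (degrees).
#' @param cellsize cell edge length in degrees (> 0).
#' @param nrow,ncol grid dimensions (>= 1).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(124, 32, 0.05, nrow = 40, ncol = 20)
#' cell_of(g, lon = 124.02, lat = 32.99)
#' @export
grid_spec <- function(xmin, ymin, cellsize, nrow, ncol) {
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0)
    stop("invalid grid: cellsize must be a positive number", call. = FALSE)
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  if (is.na(nrow) || is.na(ncol) || nrow < 1L || ncol < 1L)
    stop("invalid grid: nrow and ncol must be >= 1", call. = FALSE)
  structure(
    list(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
         cellsize = as.numeric(cellsize), nrow = nrow, ncol = ncol),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g deg, lon [%g, %g], lat [%g, %g]\n",
              x$nrow, x$ncol, x$cellsize,
              x$xmin, x$xmin + x$ncol * x$cellsize,
              x$ymin, x$ymin + x$nrow * x$cellsize))
  invisible(x)
}

is_grid_spec <- function(x) inherits(x, "grid_spec")

same_grid <- function(a, b, tol = 1e-9) {
  is_grid_spec(a) && is_grid_spec(b) &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol &&
    a$nrow == b$nrow && a$ncol == b$ncol
}

#' Cell-centre coordinates of a grid
#'
#' @param grid a [grid_spec()].
#' @return `cell_lons()`/`cell_lats()` return the centre coordinate of each
#'   column / row; `lat_matrix()` returns an `nrow x ncol` matrix of cell
#'   centre latitudes.
#' @export
cell_lons <- function(grid) grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cellsize

#' @rdname cell_lons
#' @export
cell_lats <- function(grid) grid$ymin + (seq_len(grid$nrow) - 0.5) * grid$cellsize

#' @rdname cell_lons
#' @export
lat_matrix <- function(grid) matrix(cell_lats(grid), grid$nrow, grid$ncol)

#' Map points to grid cells
#'
#' Uses the half-open cell convention (west/south edges included, east/north
#' excluded) with the grid's outermost east/north boundary closed, so every
#' in-bounds point maps to exactly one cell.
#'
#' @param grid a [grid_spec()].
#' @param lon,lat numeric vectors of point coordinates (degrees).
#' @return A data.frame with integer columns `row`, `col` (NA for points
#'   outside the grid).
#' @export
cell_of <- function(grid, lon, lat) {
  # small forward epsilon so points computed to be exactly on a boundary
  # land in the upper cell despite floating-point round-off
  col <- floor((lon - grid$xmin) / grid$cellsize + 1e-6) + 1
  row <- floor((lat - grid$ymin) / grid$cellsize + 1e-6) + 1
  xmax <- grid$xmin + grid$ncol * grid$cellsize
  ymax <- grid$ymin + grid$nrow * grid$cellsize
  col[lon == xmax] <- grid$ncol   # closed outer boundary
  row[lat == ymax] <- grid$nrow
  bad <- lon < grid$xmin | lon > xmax | lat < grid$ymin | lat > ymax
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

# Linear index into a [nrow, ncol] matrix for (row, col) pairs; NA propagates.
cell_linear_index <- function(grid, row, col) {
  (col - 1L) * grid$nrow + row
}
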