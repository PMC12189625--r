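#' Five-level habitat suitability classes
#'
#' Left-closed/right-open bins with the top bin closed:
#' Unsuitability \[0, 0.2), Low \[0.2, 0.4), Moderate \[0.4, 0.6),
#' High \[0.6, 0.8), Optimal \[0.8, 1\]. The 0.4 boundary is assigned
#' upward so the class rule and the `HSI >= 0.4` binary suitability rule
#' agree exactly at the boundary.
#'
#' @export
HSI_CLASSES <- c("Unsuitability", "Low suitability", "Moderate suitability",
                 "High suitability", "Optimal suitability")

#' Classify HSI values into the 5-level scheme
#'
#' @param hsi numeric values in \[0, 1\] (NA passed through).
#' @return factor with levels [HSI_CLASSES].
#' @export
classify_hsi <- function(hsi) {
  bad <- !is.na(hsi) & (hsi < 0 | hsi > 1)
  if (any(bad)) stop("HSI values must lie in [0, 1]", call. = FALSE)
  cls <- cut(hsi, breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1),
             labels = HSI_CLASSES, right = FALSE, include.lowest = TRUE)
  # cut(right = FALSE) puts 1.0 in no bin unless include.lowest closes the
  # top; with right = FALSE include.lowest closes the *last* interval, which
  # is what the top-bin convention requires.
  cls
}

#' Mean HSI over replicate models projected onto a stack
#'
#' Per-cell mean of the replicate predictions (replicate averaging happens
#' at native resolution, before any spatial aggregation).
#'
#' @param models list of fitted `maxent_model`s sharing a variable set.
#' @param stack an [env_stack()] holding those variables.
#' @param type output transform (`"logistic"` is the HSI used throughout).
#' @return Matrix of mean scores (NA on masked cells).
#' @export
project_hsi <- function(models, stack, type = "logistic") {
  stopifnot(length(models) >= 1)
  acc <- NULL
  for (m in models) {
    # scenario layers routinely exceed the training background range; the
    # clamped (MaxEnt-style) transfer is the intended behaviour here
    s <- suppressWarnings(predict(m, stack, type = type))
    acc <- if (is.null(acc)) s else acc + s
  }
  acc / length(models)
}

#' Aggregate a native-resolution HSI field to blocks
#'
#' Each `factor x factor` cell block (default 4 x 4, i.e. 0.2 degree blocks
#' from a 0.05 degree grid) is summarized by the mean over its unmasked
#' cells; blocks with no unmasked cell are invalid. The grid dimensions
#' must be multiples of `factor`.
#'
#' @param hsi matrix of cell HSI values (NA = masked).
#' @param grid the native [grid_spec()].
#' @param factor cells per block edge.
#' @return A `suitability_grid`: block [grid_spec()], `hsi`, `valid`,
#'   `class` and logical `suitable` (`HSI >= 0.4`) matrices.
#' @export
block_average <- function(hsi, grid, factor = 4L) {
  factor <- as.integer(factor)
  if (grid$nrow %% factor != 0 || grid$ncol %% factor != 0)
    stop(sprintf("alignment error: grid %d x %d is not divisible into %d-cell blocks",
                 grid$nrow, grid$ncol, factor), call. = FALSE)
  nr <- grid$nrow %/% factor; nc <- grid$ncol %/% factor
  bg <- grid_spec(grid$xmin, grid$ymin, grid$cellsize * factor, nr, nc)
  bh <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    cells <- hsi[((i - 1L) * factor + 1L):(i * factor),
                 ((j - 1L) * factor + 1L):(j * factor)]
    if (any(!is.na(cells))) bh[i, j] <- mean(cells, na.rm = TRUE)
  }
  suitability_grid(bg, bh)
}

#' Construct a suitability grid from block HSI values
#'
#' @param grid block-level [grid_spec()].
#' @param hsi matrix of block HSI values (NA = invalid block).
#' @return A `suitability_grid`.
#' @export
suitability_grid <- function(grid, hsi) {
  stopifnot(is_grid_spec(grid),
            identical(dim(hsi), c(grid$nrow, grid$ncol)))
  cls <- classify_hsi(hsi)
  structure(list(grid = grid, hsi = hsi, valid = !is.na(hsi),
                 class = matrix(cls, grid$nrow, grid$ncol),
                 suitable = !is.na(hsi) & hsi >= 0.4),
            class = "suitability_grid")
}

#' @export
print.suitability_grid <- function(x, ...) {
  cat(sprintf("<suitability_grid> %d x %d blocks of %g deg, %d valid, %d suitable\n",
              x$grid$nrow, x$grid$ncol, x$grid$cellsize,
              sum(x$valid), sum(x$suitable)))
  invisible(x)
}

#' Write a suitability grid as a per-block CSV
#'
#' Columns: `lon`, `lat`, `hsi`, `class`, `suitable` (valid blocks only).
#'
#' @param sg a `suitability_grid`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_suitability_csv <- function(sg, path) {
  g <- sg$grid
  idx <- which(sg$valid)
  row <- ((idx - 1L) %% g$nrow) + 1L
  col <- ((idx - 1L) %/% g$nrow) + 1L
  df <- data.table::data.table(
    lon = g$xmin + (col - 0.5) * g$cellsize,
    lat = g$ymin + (row - 0.5) * g$cellsize,
    hsi = sg$hsi[idx],
    class = as.character(sg$class[idx]),
    suitable = sg$suitable[idx])
  data.table::fwrite(df[order(df$lon, df$lat), ], path)
  invisible(path)
}
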