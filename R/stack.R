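#' The nine environmental variables used by the models
#'
#' Long-term mean, minimum (`ltmin`) and maximum (`ltmax`) of sea-surface
#' temperature (degC) and salinity (PSU), plus mean surface current velocity
#' (m s^-1), mean net primary productivity and mean nitrate concentration
#' (layer-native units).
#'
#' @export
ENV_VARIABLES <- c("temp_mean", "temp_ltmin", "temp_ltmax",
                   "sal_mean", "sal_ltmin", "sal_ltmax",
                   "vel_mean", "pp_mean", "no3_mean")

#' Build an aligned stack of environmental layers
#'
#' An `env_stack` bundles named layer matrices on a shared [grid_spec()] with
#' a single validity mask: a cell is part of the modelling domain only where
#' the mask is `TRUE`, and every layer must be finite there. Masked cells are
#' set to `NA` in every layer so the mask is identical across layers.
#'
#' @param grid a [grid_spec()].
#' @param layers named list of `nrow x ncol` numeric matrices.
#' @param mask logical `nrow x ncol` matrix (`TRUE` = valid); defaults to all
#'   cells where every layer is finite.
#' @param depth optional bathymetry matrix (metres, positive down), carried
#'   along for masking provenance.
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(grid, layers, mask = NULL, depth = NULL) {
  stopifnot(is_grid_spec(grid), is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("layers must be a named list", call. = FALSE)
  dims <- c(grid$nrow, grid$ncol)
  for (nm in names(layers)) {
    layers[[nm]] <- as.matrix(layers[[nm]])
    if (!identical(dim(layers[[nm]]), as.integer(dims)))
      stop(sprintf("layer '%s' dimensions do not match the grid", nm), call. = FALSE)
  }
  finite <- Reduce(`&`, lapply(layers, is.finite))
  if (is.null(mask)) mask <- finite else mask <- mask & finite
  mask <- matrix(as.logical(mask), dims[1], dims[2])
  for (nm in names(layers)) layers[[nm]][!mask] <- NA_real_
  structure(list(grid = grid, layers = layers, mask = mask, depth = depth),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers (%s) on %d x %d grid, %d valid cells\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$grid$nrow, x$grid$ncol, sum(x$mask)))
  invisible(x)
}

#' @rdname env_stack
#' @param x an object.
#' @export
is_env_stack <- function(x) inherits(x, "env_stack")

#' Extract the valid-cell design matrix of a stack
#'
#' @param stack an [env_stack()].
#' @param variables variables to extract (default: all layers).
#' @return A numeric matrix with one row per unmasked cell (column-major cell
#'   order) and one column per variable; the attribute `"cell_index"` holds
#'   the linear index of each row's cell.
#' @export
stack_design <- function(stack, variables = names(stack$layers)) {
  missing <- setdiff(variables, names(stack$layers))
  if (length(missing))
    stop("variables not present in stack: ", paste(missing, collapse = ", "),
         call. = FALSE)
  idx <- which(stack$mask)
  out <- matrix(NA_real_, length(idx), length(variables),
                dimnames = list(NULL, variables))
  for (v in variables) out[, v] <- stack$layers[[v]][idx]
  attr(out, "cell_index") <- idx
  out
}

#' Read and write environmental stacks as wide CSV grids
#'
#' One row per cell with columns `lon`, `lat`, `mask`, optionally `depth`,
#' then one column per variable. Round-trips values to better than 1e-6.
#'
#' @param stack an [env_stack()].
#' @param path CSV file path.
#' @return `read_stack_csv()` returns an [env_stack()]; `write_stack_csv()`
#'   returns `path` invisibly.
#' @export
write_stack_csv <- function(stack, path) {
  g <- stack$grid
  df <- data.table::data.table(
    lon = rep(cell_lons(g), each = g$nrow),
    lat = rep(cell_lats(g), times = g$ncol),
    mask = as.integer(as.vector(stack$mask)))
  if (!is.null(stack$depth)) df$depth <- as.vector(stack$depth)
  for (nm in names(stack$layers)) df[[nm]] <- as.vector(stack$layers[[nm]])
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("lon", "lat", "mask")
  if (!all(need %in% names(df)))
    stop("stack CSV must have columns lon, lat, mask", call. = FALSE)
  lons <- sort(unique(df$lon)); lats <- sort(unique(df$lat))
  cs <- if (length(lons) > 1) min(diff(lons)) else if (length(lats) > 1) min(diff(lats)) else
    stop("cannot infer cell size from a single-cell CSV", call. = FALSE)
  grid <- grid_spec(min(lons) - cs / 2, min(lats) - cs / 2, cs,
                    nrow = length(lats), ncol = length(lons))
  ord <- order(df$lon, df$lat)   # column-major: lon outer, lat inner
  df <- df[ord, , drop = FALSE]
  shape <- function(v) matrix(v, grid$nrow, grid$ncol)
  vars <- setdiff(names(df), c("lon", "lat", "mask", "depth"))
  layers <- lapply(vars, function(v) shape(as.numeric(df[[v]])))
  names(layers) <- vars
  env_stack(grid, layers,
            mask = shape(df$mask == 1L),
            depth = if ("depth" %in% names(df)) shape(as.numeric(df$depth)) else NULL)
}
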