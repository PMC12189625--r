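#' Read and write MPA masks
#'
#' Marine-protected-area masks travel either as 0/1 rasters in the wide CSV
#' grid format (`lon, lat, mpa`) or as GeoJSON polygon collections.
#' Polygons are rasterized by cell-centre containment: a cell belongs to
#' the MPA iff its centre lies inside (or on the boundary of) any polygon.
#'
#' @param mask 0/1 integer matrix on `grid`.
#' @param grid a [grid_spec()].
#' @param path file path.
#' @return `write_mpa_csv()`/`write_mpa_geojson()` return `path` invisibly;
#'   the readers return a 0/1 integer matrix.
#' @name mpa_io
NULL

#' @rdname mpa_io
#' @export
write_mpa_csv <- function(mask, grid, path) {
  df <- data.table::data.table(
    lon = rep(cell_lons(grid), each = grid$nrow),
    lat = rep(cell_lats(grid), times = grid$ncol),
    mpa = as.integer(as.vector(mask)))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname mpa_io
#' @export
read_mpa_csv <- function(path, grid) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!all(c("lon", "lat", "mpa") %in% names(df)))
    stop("MPA CSV must have columns lon, lat, mpa", call. = FALSE)
  df <- df[order(df$lon, df$lat), , drop = FALSE]
  matrix(as.integer(df$mpa), grid$nrow, grid$ncol)
}

#' @rdname mpa_io
#' @param polygons list of data.frames with `lon`, `lat` ring vertices (as
#'   produced by [generate_mpa_mask()]).
#' @export
write_mpa_geojson <- function(polygons, path) {
  features <- lapply(polygons, function(p) {
    ring <- rbind(as.matrix(p[, c("lon", "lat")]),
                  as.matrix(p[1, c("lon", "lat")]))  # close the ring
    list(type = "Feature", properties = list(designation = "MPA"),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(split(ring, row(ring)[, 1])))))
  })
  doc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname mpa_io
#' @export
read_mpa_geojson <- function(path, grid) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  rings <- list()
  for (ft in doc$features) {
    geom <- ft$geometry
    polys <- switch(geom$type,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    stop("unsupported geometry type: ", geom$type, call. = FALSE))
    for (poly in polys)            # outer ring only; holes not supported
      rings[[length(rings) + 1L]] <- do.call(
        rbind, lapply(poly[[1]], function(pt) c(pt[[1]], pt[[2]])))
  }
  lon <- rep(cell_lons(grid), each = grid$nrow)
  lat <- rep(cell_lats(grid), times = grid$ncol)
  inside <- rep(FALSE, length(lon))
  for (r in rings)
    inside <- inside | sp::point.in.polygon(lon, lat, r[, 1], r[, 2]) > 0
  matrix(as.integer(inside), grid$nrow, grid$ncol)
}
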