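#' Occurrence sets
#'
#' An `occurrence_set` is a data.frame of presence records with columns
#' `species`, `lon`, `lat`, `year` and a derived `era` factor: records dated
#' before 2000 belong to the `past` era, records from 2000 onwards to the
#' `present` era. The `dedup` attribute records whether the set has been
#' thinned to one record per grid cell.
#'
#' @param df data.frame with columns `species`, `lon`, `lat`, `year`.
#' @param dedup logical; has per-cell thinning been applied?
#' @return An `occurrence_set`.
#' @export
occurrence_set <- function(df, dedup = FALSE) {
  need <- c("species", "lon", "lat", "year")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("occurrence data must have columns ",
         paste(need, collapse = ", "), " (missing: ",
         paste(missing, collapse = ", "), ")", call. = FALSE)
  df <- as.data.frame(df)[, need]
  rownames(df) <- NULL
  df$era <- factor(ifelse(df$year < 2000, "past", "present"),
                   levels = c("past", "present"))
  structure(df, class = c("occurrence_set", "data.frame"), dedup = dedup)
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d records, %d species (%s), dedup=%s\n",
              nrow(x), length(unique(x$species)),
              paste(sprintf("%s: %d", levels(x$era), table(x$era)), collapse = ", "),
              isTRUE(attr(x, "dedup"))))
  invisible(x)
}

#' Load occurrence records from CSV
#'
#' Expects a header `species,lon,lat,year`. Rows outside the grid bounding
#' box are dropped with a message reporting the count; unparseable rows
#' raise an error naming the offending line.
#'
#' @param path CSV file.
#' @param grid a [grid_spec()] defining the study bounding box (optional:
#'   `NULL` keeps all records).
#' @return An [occurrence_set()] (not yet deduplicated).
#' @export
load_occurrences <- function(path, grid = NULL) {
  df <- data.table::fread(path, colClasses = list(
    character = "species"), data.table = FALSE)
  need <- c("species", "lon", "lat", "year")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("occurrence CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) return(occurrence_set(df[, need]))
  for (col in c("lon", "lat", "year")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    bad <- union(bad, which(is.na(df[[col]])))
    if (length(bad))
      stop(sprintf("unparseable '%s' value on data line %d of %s",
                   col, bad[1], path), call. = FALSE)
    df[[col]] <- v
  }
  if (!is.null(grid)) {
    idx <- cell_of(grid, df$lon, df$lat)
    drop <- is.na(idx$row)
    if (any(drop))
      message(sum(drop), " record(s) outside the grid bounding box dropped")
    df <- df[!drop, , drop = FALSE]
  }
  occurrence_set(df)
}

#' Write an occurrence set as CSV
#' @param occ an [occurrence_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  data.table::fwrite(as.data.frame(occ)[, c("species", "lon", "lat", "year")],
                     path)
  invisible(path)
}

#' Thin occurrences to one record per grid cell
#'
#' If several records of the same species and era fall inside one
#' `cell x cell` degree interval, only the first (in file order) is kept.
#' Cells live on the absolute lon/lat lattice anchored at (0, 0), with the
#' half-open membership convention. Idempotent.
#'
#' @param occ an [occurrence_set()].
#' @param cell thinning interval in degrees (default 0.05).
#' @return A deduplicated [occurrence_set()].
#' @export
dedup_to_grid <- function(occ, cell = 0.05) {
  stopifnot(inherits(occ, "occurrence_set"), cell > 0)
  if (nrow(occ) == 0) return(occurrence_set(as.data.frame(occ), dedup = TRUE))
  key <- paste(occ$species, occ$era,
               floor(occ$lon / cell + 1e-6), floor(occ$lat / cell + 1e-6))
  keep <- !duplicated(key)
  occurrence_set(as.data.frame(occ)[keep, , drop = FALSE], dedup = TRUE)
}

#' Extract environmental values at occurrence points
#'
#' Each record is mapped to its grid cell; records on masked (or
#' out-of-grid) cells are dropped with a message reporting the count.
#'
#' @param stack an [env_stack()].
#' @param occ a deduplicated [occurrence_set()].
#' @param variables variables to extract, in the requested column order
#'   (default all stack layers).
#' @return Matrix (records x variables); attribute `"dropped"` holds the
#'   number of discarded records and `"cell_index"` the linear cell index of
#'   each retained row.
#' @export
extract_at_points <- function(stack, occ, variables = names(stack$layers)) {
  stopifnot(is_env_stack(stack), inherits(occ, "occurrence_set"))
  missing <- setdiff(variables, names(stack$layers))
  if (length(missing))
    stop("variables not present in stack: ", paste(missing, collapse = ", "),
         call. = FALSE)
  rc <- cell_of(stack$grid, occ$lon, occ$lat)
  lin <- cell_linear_index(stack$grid, rc$row, rc$col)
  ok <- !is.na(lin) & stack$mask[ifelse(is.na(lin), 1L, lin)]
  if (any(!ok))
    message(sum(!ok), " record(s) on masked or out-of-grid cells dropped")
  lin <- lin[ok]
  if (length(lin) == 0)
    stop("empty design: all occurrence records fall on masked cells",
         call. = FALSE)
  out <- vapply(variables, function(v) stack$layers[[v]][lin],
                numeric(length(lin)))
  out <- matrix(out, nrow = length(lin), dimnames = list(NULL, variables))
  attr(out, "dropped") <- sum(!ok)
  attr(out, "cell_index") <- lin
  out
}
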