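#' Degrees-to-kilometres constant (spherical Earth, authalic radius)
#' @export
KM_PER_DEGREE <- 111.195

#' Change categories between present and future suitability
#'
#' Truth table on the binary suitability flags of a valid block:
#' Absence (unsuitable in both), Constriction (suitable to unsuitable),
#' Expansion (unsuitable to suitable), Stability (suitable in both).
#'
#' @param present,future logical vectors/matrices of suitability flags
#'   (NA = invalid block; excluded, not categorized).
#' @return factor (same shape) with the four category levels.
#' @export
change_category <- function(present, future) {
  lv <- c("Absence", "Constriction", "Expansion", "Stability")
  out <- ifelse(is.na(present) | is.na(future), NA_character_,
         ifelse(present & future, "Stability",
         ifelse(present & !future, "Constriction",
         ifelse(!present & future, "Expansion", "Absence"))))
  if (is.matrix(present)) {
    res <- matrix(factor(out, levels = lv), nrow(present), ncol(present))
    res
  } else factor(out, levels = lv)
}

# Spherical-rectangle area of each block (km^2): a cellsize x cellsize
# degree block at latitude phi covers (cs*111.195) * (cs*111.195*cos(phi)).
block_areas_km2 <- function(grid) {
  lat <- lat_matrix(grid)
  (grid$cellsize * KM_PER_DEGREE)^2 * cos(lat * pi / 180)
}

#' Suitable-habitat area
#'
#' Sums the cosine-weighted spherical block areas of suitable blocks;
#' also returns the per-latitude-band breakdown (one band per block row).
#'
#' @param sg a [suitability_grid()].
#' @return list with `total_km2` and `by_latitude` (data.frame `lat`,
#'   `area_km2`).
#' @export
suitable_area <- function(sg) {
  stopifnot(inherits(sg, "suitability_grid"))
  a <- block_areas_km2(sg$grid)
  a[!sg$suitable] <- 0
  list(total_km2 = sum(a),
       by_latitude = data.frame(lat = cell_lats(sg$grid),
                                area_km2 = rowSums(a)))
}

#' Percent trend between present and future area
#'
#' `100 * (future - present) / present`; undefined (NA) when the present
#' area is not positive.
#'
#' @param present,future areas in any common unit.
#' @return Trend in percent (full precision; round to 2 decimals for
#'   reporting).
#' @export
trend_percent <- function(present, future) {
  ifelse(present > 0, 100 * (future - present) / present, NA_real_)
}

#' HSI-weighted latitudinal centroid
#'
#' Mean block-centre latitude weighted by block HSI over all valid blocks
#' (not only suitable ones); undefined (NA) when every valid block has
#' zero HSI.
#'
#' @param sg a [suitability_grid()].
#' @return Centroid latitude in degrees north, or NA.
#' @export
weighted_centroid <- function(sg) {
  stopifnot(inherits(sg, "suitability_grid"))
  w <- sg$hsi
  w[!sg$valid] <- 0
  if (sum(w, na.rm = TRUE) <= 0) return(NA_real_)
  lat <- lat_matrix(sg$grid)
  sum(lat * w, na.rm = TRUE) / sum(w, na.rm = TRUE)
}

#' Multi-species richness grid
#'
#' Counts, per block, the species whose habitat-suitability flag is set;
#' zero-richness blocks are the "Absence" class.
#'
#' @param grids named list of [suitability_grid()]s on one block grid.
#' @return list with `richness` (integer matrix, NA on blocks valid for no
#'   species), `valid`, and the block `grid`.
#' @export
richness <- function(grids) {
  stopifnot(length(grids) >= 1)
  g <- grids[[1]]$grid
  for (sg in grids)
    if (!same_grid(sg$grid, g))
      stop("alignment error: suitability grids are on different blocks",
           call. = FALSE)
  counts <- Reduce(`+`, lapply(grids, function(sg) {
    m <- matrix(0L, g$nrow, g$ncol); m[sg$suitable] <- 1L; m
  }))
  valid <- Reduce(`|`, lapply(grids, function(sg) sg$valid))
  counts[!valid] <- NA_integer_
  list(richness = counts, valid = valid, grid = g)
}

#' MPA overlap classes and protected fraction
#'
#' A block is inside the MPA when any of its constituent native-resolution
#' cells is flagged. Classes: `Absence` (richness 0), `Protected`
#' (richness >= 1 and inside the MPA), `Unprotected` (richness >= 1,
#' outside). The protected fraction is the Protected blocks' area divided
#' by the total suitable (Protected + Unprotected) area, in percent.
#'
#' @param rich output of [richness()].
#' @param mpa_mask 0/1 matrix, either on the block grid or on the native
#'   grid (any-of-cells rule applied when finer).
#' @param mpa_grid the [grid_spec()] of `mpa_mask` (defaults to the block
#'   grid).
#' @return list with `class` (character matrix), `protected_fraction`
#'   (percent), and per-class areas (km^2).
#' @export
mpa_overlap <- function(rich, mpa_mask, mpa_grid = rich$grid) {
  g <- rich$grid
  if (same_grid(mpa_grid, g)) {
    inmpa <- mpa_mask > 0
  } else {
    factor <- round(g$cellsize / mpa_grid$cellsize)
    if (abs(mpa_grid$cellsize * factor - g$cellsize) > 1e-9 ||
        mpa_grid$nrow != g$nrow * factor || mpa_grid$ncol != g$ncol * factor)
      stop("alignment error: MPA mask grid does not nest in the block grid",
           call. = FALSE)
    inmpa <- matrix(FALSE, g$nrow, g$ncol)
    for (i in seq_len(g$nrow)) for (j in seq_len(g$ncol))
      inmpa[i, j] <- any(mpa_mask[((i - 1L) * factor + 1L):(i * factor),
                                  ((j - 1L) * factor + 1L):(j * factor)] > 0)
  }
  cls <- matrix(NA_character_, g$nrow, g$ncol)
  occupied <- !is.na(rich$richness) & rich$richness >= 1L
  empty <- !is.na(rich$richness) & rich$richness == 0L
  cls[empty] <- "Absence"
  cls[occupied & inmpa] <- "Protected"
  cls[occupied & !inmpa] <- "Unprotected"
  a <- block_areas_km2(g)
  area_prot <- sum(a[cls == "Protected"], na.rm = TRUE)
  area_unprot <- sum(a[cls == "Unprotected"], na.rm = TRUE)
  frac <- if (area_prot + area_unprot > 0)
    100 * area_prot / (area_prot + area_unprot) else NA_real_
  list(class = cls, protected_fraction = frac,
       area_km2 = c(Protected = area_prot, Unprotected = area_unprot,
                    Absence = sum(a[cls == "Absence"], na.rm = TRUE)))
}

#' Present-vs-future change summary for one species and scenario
#'
#' Bundles the change-category map, suitable areas (10^3 km^2), the percent
#' trend, HSI-weighted centroids and the centroid shift. Conservation
#' identities (Stability + Constriction = present suitable area;
#' Stability + Expansion = future suitable area) are asserted on every
#' call.
#'
#' @param present_sg,future_sg [suitability_grid()]s on the same blocks.
#' @param species,scenario,period labels carried into the summary.
#' @return A `change_summary` list.
#' @export
change_summary <- function(present_sg, future_sg, species = "species",
                           scenario = NA_character_, period = NA_character_) {
  if (!same_grid(present_sg$grid, future_sg$grid))
    stop("alignment error: present and future grids differ", call. = FALSE)
  pres_flag <- ifelse(present_sg$valid, present_sg$suitable, NA)
  fut_flag <- ifelse(future_sg$valid, future_sg$suitable, NA)
  cat_map <- change_category(pres_flag, fut_flag)
  a <- block_areas_km2(present_sg$grid)
  area_by_cat <- vapply(c("Absence", "Constriction", "Expansion", "Stability"),
                        function(k) sum(a[!is.na(cat_map) & cat_map == k]),
                        numeric(1))
  area_present <- suitable_area(present_sg)$total_km2
  area_future <- suitable_area(future_sg)$total_km2
  both <- !is.na(pres_flag) & !is.na(fut_flag)
  id1 <- sum(a[both & pres_flag]) - (area_by_cat[["Stability"]] + area_by_cat[["Constriction"]])
  id2 <- sum(a[both & fut_flag]) - (area_by_cat[["Stability"]] + area_by_cat[["Expansion"]])
  stopifnot(abs(id1) < 1e-6, abs(id2) < 1e-6)
  structure(list(
    species = species, scenario = scenario, period = period,
    categories = cat_map, area_by_category_km2 = area_by_cat,
    area_present = area_present / 1e3, area_future = area_future / 1e3,
    trend = trend_percent(area_present, area_future),
    centroid_present = weighted_centroid(present_sg),
    centroid_future = weighted_centroid(future_sg)),
    class = "change_summary")
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf(
    "<change_summary> %s %s %s: %.2f -> %.2f (10^3 km^2), trend %+.2f%%, centroid %.2f -> %.2f N\n",
    x$species, x$scenario, x$period, x$area_present, x$area_future,
    x$trend, x$centroid_present, x$centroid_future))
  invisible(x)
}
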