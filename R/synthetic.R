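#' Synthetic study world
#'
#' Generators for everything the pipeline consumes: spatially autocorrelated
#' environmental layers with a latitudinal temperature gradient, additive
#' climate-scenario offsets, a bathymetry-derived depth mask (20 m generally,
#' 5 m inside a high-turbidity subregion), presence records sampled from a
#' known suitability surface, and a polygonal marine-protected-area mask.
#' Every generator is deterministic given its seed.
#'
#' @name synthetic
NULL

#' Default study-area grid
#'
#' A 0.05 degree lattice spanning 124-132 E, 32-44 N (the temperate
#' western-North-Pacific shelf the package emulates).
#'
#' @return A [grid_spec()].
#' @export
default_grid <- function() grid_spec(124, 32, 0.05, nrow = 240, ncol = 160)

# Separable Gaussian smoothing with reflection padding; the workhorse for
# spatial autocorrelation (kernel sd in cells).
gauss_smooth <- function(m, sd_cells = 3) {
  r <- ceiling(3 * sd_cells)
  k <- stats::dnorm(-r:r, sd = sd_cells)
  k <- k / sum(k)
  smooth_vec <- function(v) {
    n <- length(v)
    pad <- c(rev(v[seq_len(min(r, n))]), v, rev(v[seq.int(n, by = -1, length.out = min(r, n))]))
    if (length(pad) < n + 2 * r)  # tiny dimension: recycle reflection
      pad <- rep_len(pad, n + 2 * r)
    stats::filter(pad, k, sides = 2)[(r + 1):(r + n)]
  }
  m <- apply(m, 2, smooth_vec)
  t(apply(t(m), 2, smooth_vec))
}

# Standardized smoothed white-noise field (mean 0, sd 1).
smooth_noise <- function(grid, sd_cells = 3) {
  z <- matrix(stats::rnorm(grid$nrow * grid$ncol), grid$nrow, grid$ncol)
  z <- gauss_smooth(z, sd_cells)
  (z - mean(z)) / stats::sd(z)
}

# Deterministic (noise-free) components of every layer. Temperature declines
# 0.5 degC per degree latitude from a 22 degC southern edge; salinity,
# productivity and nitrate carry mild gradients of their own.
deterministic_layers <- function(grid) {
  lat <- lat_matrix(grid)
  dlat <- lat - grid$ymin
  tmean <- 22 - 0.5 * dlat
  smean <- 33 - 0.03 * dlat
  list(
    temp_mean  = tmean,
    temp_ltmin = tmean - 6,
    temp_ltmax = tmean + 6,
    sal_mean   = smean,
    sal_ltmin  = smean - 1.5,
    sal_ltmax  = smean + 1.0,
    vel_mean   = 0.45 + 0.01 * (dlat - mean(dlat)),
    pp_mean    = 0.60 + 0.01 * dlat,
    no3_mean   = 2.0 + 0.15 * dlat)
}

#' Generate a synthetic environmental layer stack
#'
#' Each layer is a smooth deterministic gradient plus `noise_sd` times a
#' spatially autocorrelated standardized noise field (Gaussian kernel
#' smoothing of white noise, kernel sd 3 cells). Nuisance layers share part
#' of their noise with temperature or salinity so the variable-screening
#' step has realistic collinearity to deal with. By construction
#' `temp_ltmin <= temp_mean <= temp_ltmax` (and likewise for salinity) in
#' every cell.
#'
#' @param grid a [grid_spec()] at 0.05 degree resolution.
#' @param seed integer RNG seed.
#' @param noise_sd non-negative scale of the autocorrelated noise
#'   (degC on temperature layers; other layers use scaled-down versions).
#' @param mask optional logical validity mask to apply (e.g. from
#'   [generate_bathymetry_and_mask()]).
#' @return An [env_stack()] with the nine [ENV_VARIABLES] layers.
#' @export
generate_env_stack <- function(grid, seed = 1L, noise_sd = 1, mask = NULL) {
  if (!is_grid_spec(grid)) stop("invalid grid", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  base <- deterministic_layers(grid)
  set.seed(seed)
  z <- replicate(8, smooth_noise(grid), simplify = FALSE)
  names(z) <- c("t", "tr1", "tr2", "s", "v", "p", "n", "sr")
  # partly correlated nuisance noise
  zp <- 0.6 * z$t + 0.8 * z$p
  zn <- 0.5 * z$s + sqrt(1 - 0.25) * z$n
  zs <- 0.5 * z$t + sqrt(1 - 0.25) * z$s
  layers <- list(
    temp_mean  = base$temp_mean + noise_sd * z$t,
    temp_ltmin = base$temp_mean + noise_sd * z$t - 6 - abs(noise_sd * z$tr1),
    temp_ltmax = base$temp_mean + noise_sd * z$t + 6 + abs(noise_sd * z$tr2),
    sal_mean   = base$sal_mean + 0.4 * noise_sd * zs,
    sal_ltmin  = base$sal_mean + 0.4 * noise_sd * zs - 1.5 - abs(0.3 * noise_sd * z$sr),
    sal_ltmax  = base$sal_mean + 0.4 * noise_sd * zs + 1.0 + abs(0.3 * noise_sd * z$sr),
    vel_mean   = pmax(base$vel_mean + 0.25 * noise_sd * z$v, 0.02),
    pp_mean    = pmax(base$pp_mean + 0.15 * noise_sd * zp, 0.05),
    no3_mean   = pmax(base$no3_mean + 0.5 * noise_sd * zn, 0.05))
  env_stack(grid, layers, mask = mask)
}

#' Climate-scenario specification
#'
#' Additive layer offsets for a Shared Socioeconomic Pathway and future
#' period, emulating scenario anomaly layers relative to a present baseline.
#' Warming offsets increase with both emission severity and period
#' (SSP1-1.9 <= SSP2-4.5 <= SSP5-8.5 at equal period; non-decreasing in
#' period within a scenario); salinity, productivity and nitrate decline
#' mildly with severity.
#'
#' @param scenario one of `"SSP1-1.9"`, `"SSP2-4.5"`, `"SSP5-8.5"`.
#' @param period one of `"2030s"`, `"2060s"`, `"2090s"`.
#' @return An object of class `scenario_spec` with an `offsets` vector
#'   (one entry per [ENV_VARIABLES]; temperature offsets in degC).
#' @export
scenario_spec <- function(scenario, period) {
  scenarios <- c("SSP1-1.9", "SSP2-4.5", "SSP5-8.5")
  periods <- c("2030s", "2060s", "2090s")
  if (!scenario %in% scenarios)
    stop("unknown scenario '", scenario, "'", call. = FALSE)
  if (!period %in% periods)
    stop("unknown period '", period, "'", call. = FALSE)
  # rows: scenario, cols: period (degC sea-surface warming vs 2000-2020)
  warming <- matrix(c(0.6, 0.9, 1.0,
                      0.8, 1.6, 2.4,
                      1.0, 2.4, 4.3), 3, 3, byrow = TRUE,
                    dimnames = list(scenarios, periods))
  freshening <- matrix(c(-0.05, -0.08, -0.10,
                         -0.08, -0.15, -0.25,
                         -0.10, -0.30, -0.50), 3, 3, byrow = TRUE,
                       dimnames = list(scenarios, periods))
  dT <- warming[scenario, period]
  dS <- freshening[scenario, period]
  offsets <- c(temp_mean = dT, temp_ltmin = dT, temp_ltmax = dT,
               sal_mean = dS, sal_ltmin = dS, sal_ltmax = dS,
               vel_mean = 0,
               pp_mean = 0.04 * dS,       # productivity tracks freshening mildly
               no3_mean = 0.4 * dS)
  structure(list(scenario = scenario, period = period, offsets = offsets),
            class = "scenario_spec")
}

#' All nine scenario x period combinations
#' @return data.frame with columns `scenario`, `period`.
#' @export
scenario_table <- function() {
  expand.grid(scenario = c("SSP1-1.9", "SSP2-4.5", "SSP5-8.5"),
              period = c("2030s", "2060s", "2090s"),
              stringsAsFactors = FALSE)[, c("scenario", "period")]
}

#' Apply a climate scenario to a stack
#'
#' Adds the scenario's per-variable offsets; the validity mask is unchanged.
#'
#' @param stack an [env_stack()].
#' @param spec a [scenario_spec()].
#' @return The offset [env_stack()].
#' @export
apply_scenario <- function(stack, spec) {
  stopifnot(is_env_stack(stack), inherits(spec, "scenario_spec"))
  layers <- stack$layers
  for (nm in names(layers)) {
    off <- spec$offsets[[nm]]
    if (!is.null(off) && !is.na(off)) layers[[nm]] <- layers[[nm]] + off
  }
  env_stack(stack$grid, layers, mask = stack$mask, depth = stack$depth)
}

#' Generate bathymetry and the depth-based validity mask
#'
#' Depth increases smoothly with distance from the synthetic coastline (the
#' western grid edge) plus autocorrelated noise, producing a coastal ribbon.
#' Cells deeper than `depth_limit` (20 m) are masked; inside the
#' high-turbidity bounding box `turbid_region` the limit tightens to
#' `turbid_limit` (5 m).
#'
#' @param grid a [grid_spec()].
#' @param seed RNG seed.
#' @param turbid_region optional `c(xmin, xmax, ymin, ymax)` bounding box
#'   (degrees) of the turbid subregion; must intersect the grid.
#' @param slope deterministic depth increase per cell away from the coast (m).
#' @param noise_sd sd of the autocorrelated depth noise (m).
#' @param depth_limit,turbid_limit depth cut-offs (m).
#' @return list with `depth` (matrix, m) and `mask` (logical matrix).
#' @export
generate_bathymetry_and_mask <- function(grid, seed = 1L, turbid_region = NULL,
                                         slope = 0.9, noise_sd = 3,
                                         depth_limit = 20, turbid_limit = 5) {
  set.seed(seed + 1000L)
  dist <- matrix(rep(seq_len(grid$ncol) - 1L, each = grid$nrow),
                 grid$nrow, grid$ncol)
  depth <- pmax(slope * dist + noise_sd * smooth_noise(grid), 0)
  mask <- depth <= depth_limit
  if (!is.null(turbid_region)) {
    stopifnot(length(turbid_region) == 4)
    lon <- matrix(rep(cell_lons(grid), each = grid$nrow), grid$nrow, grid$ncol)
    lat <- lat_matrix(grid)
    inbox <- lon >= turbid_region[1] & lon <= turbid_region[2] &
      lat >= turbid_region[3] & lat <= turbid_region[4]
    if (!any(inbox))
      stop("turbid_region does not intersect the grid", call. = FALSE)
    mask[inbox & depth > turbid_limit] <- FALSE
  }
  list(depth = depth, mask = mask)
}

#' A known ("true") suitability surface
#'
#' Suitability is the logistic transform of a quadratic form in two driver
#' variables: winter temperature (`temp_ltmin`), with a quadratic optimum,
#' and current velocity (`vel_mean`), increasing up to a saturation cap of
#' 0.7 m s^-1 and flat beyond it. Coefficients are stored so the surface is
#' deterministic given a stack.
#'
#' @param t_opt optimal winter temperature (degC).
#' @param t_curv curvature of the temperature response (logits per degC^2).
#' @param v_slope velocity effect (logits across the 0-0.7 m s^-1 range).
#' @param v_cap saturation velocity (m s^-1).
#' @param intercept baseline logit.
#' @return An object of class `true_surface`.
#' @export
true_surface <- function(t_opt = 12, t_curv = 1.0, v_slope = 8,
                         v_cap = 0.7, intercept = -2.5) {
  structure(list(drivers = c("temp_ltmin", "vel_mean"),
                 t_opt = t_opt, t_curv = t_curv, v_slope = v_slope,
                 v_cap = v_cap, intercept = intercept),
            class = "true_surface")
}

#' Evaluate a true suitability surface on a stack
#'
#' @param surface a [true_surface()].
#' @param stack an [env_stack()] containing the driver layers.
#' @return Matrix of suitabilities in \[0, 1\] (NA on masked cells).
#' @export
true_suitability <- function(surface, stack) {
  stopifnot(inherits(surface, "true_surface"), is_env_stack(stack))
  tmin <- stack$layers$temp_ltmin
  vel <- pmin(stack$layers$vel_mean, surface$v_cap)
  eta <- surface$intercept -
    surface$t_curv * (tmin - surface$t_opt)^2 +
    (surface$v_slope / surface$v_cap) * (vel - surface$v_cap / 2)
  s <- stats::plogis(eta)
  s[!stack$mask] <- NA_real_
  s
}

#' Sample presence records from a known suitability surface
#'
#' Cells are drawn (with replacement) with probability proportional to true
#' suitability among unmasked cells; coordinates are jittered uniformly
#' within the chosen cell; years are assigned so that both the past
#' (pre-2000) and present (post-2000) eras are represented.
#'
#' @param surface a [true_surface()].
#' @param stack an [env_stack()].
#' @param n number of records (>= 1).
#' @param seed RNG seed.
#' @param species species label for the records.
#' @param past_fraction expected fraction of records dated before 2000.
#' @return An occurrence set (see [load_occurrences()]).
#' @export
sample_occurrences <- function(surface, stack, n, seed = 1L,
                               species = "species_1", past_fraction = 0.25) {
  stopifnot(n >= 1)
  s <- true_suitability(surface, stack)
  idx <- which(stack$mask & s > 0)
  if (length(idx) == 0)
    stop("degenerate surface: no unmasked cell has positive suitability",
         call. = FALSE)
  set.seed(seed)
  pick <- idx[sample.int(length(idx), n, replace = TRUE, prob = s[idx])]
  g <- stack$grid
  row <- ((pick - 1L) %% g$nrow) + 1L
  col <- ((pick - 1L) %/% g$nrow) + 1L
  lon <- g$xmin + (col - 1L + stats::runif(n)) * g$cellsize
  lat <- g$ymin + (row - 1L + stats::runif(n)) * g$cellsize
  past <- stats::runif(n) < past_fraction
  if (!any(past)) past[1] <- TRUE      # both eras represented
  if (all(past)) past[1] <- FALSE
  year <- ifelse(past, sample(1970:1999, n, replace = TRUE),
                 sample(2000:2022, n, replace = TRUE))
  occurrence_set(data.frame(species = species, lon = lon, lat = lat,
                            year = year, stringsAsFactors = FALSE))
}

#' Generate a polygonal marine-protected-area mask
#'
#' Random rectangular patches (contiguous cell blocks) are added over the
#' valid domain until the requested coverage fraction of unmasked cells is
#' reached; patch sizes are small relative to the target so realized
#' coverage stays within about 20 percent (relative) of the request.
#'
#' @param grid a [grid_spec()].
#' @param seed RNG seed.
#' @param coverage_fraction target fraction of unmasked cells inside an MPA,
#'   in (0, 1).
#' @param mask logical validity mask (default: whole grid valid).
#' @return list with `mask` (0/1 integer matrix) and `polygons` (list of
#'   rectangle corner data.frames, lon/lat, for GeoJSON export).
#' @export
generate_mpa_mask <- function(grid, seed = 1L, coverage_fraction = 0.3,
                              mask = NULL) {
  if (!is.numeric(coverage_fraction) || coverage_fraction <= 0 ||
      coverage_fraction >= 1)
    stop("coverage_fraction must be in (0, 1)", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, grid$nrow, grid$ncol)
  valid_idx <- which(mask)
  target <- coverage_fraction * length(valid_idx)
  max_half <- max(1L, floor(sqrt(0.15 * target) / 2))
  set.seed(seed + 2000L)
  mpa <- matrix(0L, grid$nrow, grid$ncol)
  polys <- list()
  guard <- 0L
  # add patches until 95% of the target is covered; reject a patch that
  # would overshoot 120%, so realized coverage lands within +-20% relative
  while (sum(mpa[valid_idx]) < 0.95 * target && guard < 20000L) {
    guard <- guard + 1L
    centre <- valid_idx[sample.int(length(valid_idx), 1L)]
    r0 <- ((centre - 1L) %% grid$nrow) + 1L
    c0 <- ((centre - 1L) %/% grid$nrow) + 1L
    hr <- sample.int(max_half, 1L); hc <- sample.int(max_half, 1L)
    rows <- max(1L, r0 - hr):min(grid$nrow, r0 + hr)
    cols <- max(1L, c0 - hc):min(grid$ncol, c0 + hc)
    cand <- mpa
    cand[rows, cols] <- 1L
    if (sum(cand[valid_idx]) > 1.2 * target) next
    mpa <- cand
    polys[[length(polys) + 1L]] <- data.frame(
      lon = grid$xmin + c(min(cols) - 1, max(cols), max(cols), min(cols) - 1) * grid$cellsize,
      lat = grid$ymin + c(min(rows) - 1, min(rows) - 1, max(rows), max(rows)) * grid$cellsize)
  }
  list(mask = mpa, polygons = polys)
}
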