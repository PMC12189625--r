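# Small synthetic world shared across test files; built once per test run.
.world_cache <- new.env(parent = emptyenv())

small_world <- function() {
  if (!is.null(.world_cache$w)) return(.world_cache$w)
  g <- grid_spec(124, 32, 0.05, nrow = 48, ncol = 32)
  bathy <- generate_bathymetry_and_mask(
    g, seed = 7, turbid_region = c(124, 124.6, 33.5, 34.4))
  stack <- generate_env_stack(g, seed = 7, mask = bathy$mask)
  stack$depth <- bathy$depth
  surf <- true_surface()
  occ <- dedup_to_grid(sample_occurrences(surf, stack, 250, seed = 7))
  occ_present <- occurrence_set(
    as.data.frame(occ)[occ$era == "present", ], dedup = TRUE)
  .world_cache$w <- list(grid = g, bathy = bathy, stack = stack,
                         surface = surf, occ = occ,
                         occ_present = occ_present)
  .world_cache$w
}

# presence/background designs for the default candidate variables
world_designs <- function(vars = c("temp_ltmin", "vel_mean", "temp_ltmax",
                                   "sal_mean", "pp_mean", "no3_mean"),
                          n_background = 1500) {
  w <- small_world()
  pres <- suppressMessages(extract_at_points(w$stack, w$occ_present, vars))
  bg <- stack_design(w$stack, vars)
  if (nrow(bg) > n_background) {
    set.seed(42)
    bg <- bg[sort(sample.int(nrow(bg), n_background)), , drop = FALSE]
  }
  list(presence = pres, background = bg)
}
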