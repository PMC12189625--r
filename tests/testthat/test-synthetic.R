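test_that("environmental stack generation is seeded, ordered and autocorrelated", {
  g <- grid_spec(124, 32, 0.05, nrow = 24, ncol = 16)
  a <- generate_env_stack(g, seed = 3)
  b <- generate_env_stack(g, seed = 3)
  expect_identical(a$layers, b$layers)
  expect_false(identical(a$layers$temp_mean,
                         generate_env_stack(g, seed = 4)$layers$temp_mean))

  # zero-noise limit: layers equal their deterministic gradient components
  z <- generate_env_stack(g, seed = 3, noise_sd = 0)
  det <- sargassdm:::deterministic_layers(g)
  for (nm in names(det))
    expect_equal(z$layers[[nm]], det[[nm]], tolerance = 1e-12,
                 ignore_attr = TRUE)

  # range ordering forced by construction, on a seeded noisy stack
  s1 <- generate_env_stack(g, seed = 1)
  expect_true(all(s1$layers$temp_ltmin <= s1$layers$temp_mean))
  expect_true(all(s1$layers$temp_mean <= s1$layers$temp_ltmax))
  expect_true(all(s1$layers$sal_ltmin <= s1$layers$sal_ltmax))

  # temperature declines with latitude in expectation: on a taller grid the
  # 0.5 degC/degree gradient dominates the unit-sd autocorrelated noise
  gt <- grid_spec(124, 32, 0.05, nrow = 120, ncol = 16)
  tall <- generate_env_stack(gt, seed = 1)$layers$temp_mean
  rowmeans <- rowMeans(tall)
  expect_lt(mean(rowmeans[101:120]), mean(rowmeans[1:20]))

  # smoothing induces positive correlation between lattice neighbours
  m <- s1$layers$temp_mean - det$temp_mean
  expect_gt(cor(as.vector(m[-1, ]), as.vector(m[-nrow(m), ])), 0.5)

  expect_error(grid_spec(124, 32, 0.05, nrow = 0, ncol = 5), "invalid grid")
  expect_error(generate_env_stack(g, noise_sd = -1), "noise_sd")
})

test_that("scenario offsets are additive, ordered, and validated", {
  g <- grid_spec(124, 32, 0.05, nrow = 12, ncol = 8)
  st <- generate_env_stack(g, seed = 2)

  zero <- scenario_spec("SSP1-1.9", "2030s")
  zero$offsets[] <- 0
  expect_equal(apply_scenario(st, zero)$layers, st$layers)

  sp <- scenario_spec("SSP2-4.5", "2060s")
  shifted <- apply_scenario(st, sp)
  expect_equal(shifted$layers$temp_mean - st$layers$temp_mean,
               matrix(sp$offsets[["temp_mean"]], g$nrow, g$ncol),
               ignore_attr = TRUE)
  expect_identical(shifted$mask, st$mask)

  # offset +3 degC constructed explicitly -> cell-wise difference exactly 3
  plus3 <- sp; plus3$offsets[] <- 0
  plus3$offsets[c("temp_mean", "temp_ltmin", "temp_ltmax")] <- 3
  expect_equal(apply_scenario(st, plus3)$layers$temp_ltmax,
               st$layers$temp_ltmax + 3)

  # monotonicity across the full scenario table
  tab <- scenario_table()
  offs <- mapply(function(s, p) scenario_spec(s, p)$offsets[["temp_mean"]],
                 tab$scenario, tab$period)
  off_m <- matrix(offs, nrow = 3, dimnames = list(unique(tab$scenario),
                                                  unique(tab$period)))
  for (r in 1:3) expect_true(!is.unsorted(off_m[r, ]))   # within scenario
  for (c in 1:3) expect_true(!is.unsorted(off_m[, c]))   # across severity
  hot <- apply_scenario(st, scenario_spec("SSP5-8.5", "2090s"))
  low <- apply_scenario(st, scenario_spec("SSP1-1.9", "2090s"))
  expect_true(all(hot$layers$temp_mean >= low$layers$temp_mean, na.rm = TRUE))

  expect_error(scenario_spec("SSP9-9.9", "2030s"), "unknown scenario")
  expect_error(scenario_spec("SSP1-1.9", "2200s"), "unknown period")
})

test_that("bathymetry masking applies the 20 m rule and the 5 m turbid rule", {
  g <- grid_spec(124, 32, 0.05, nrow = 40, ncol = 40)
  box <- c(124, 125, 33, 34)
  bt <- generate_bathymetry_and_mask(g, seed = 5, turbid_region = box)
  expect_identical(bt$mask,
                   generate_bathymetry_and_mask(g, seed = 5,
                                                turbid_region = box)$mask)
  expect_true(all(!bt$mask[bt$depth > 20]))
  expect_true(all(bt$mask[bt$depth == 0]))

  lon <- matrix(rep(cell_lons(g), each = g$nrow), g$nrow, g$ncol)
  lat <- lat_matrix(g)
  inbox <- lon >= box[1] & lon <= box[2] & lat >= box[3] & lat <= box[4]
  mid <- bt$depth > 5 & bt$depth <= 20      # 5-20 m: masked only when turbid
  expect_true(all(!bt$mask[inbox & mid]))
  expect_true(all(bt$mask[!inbox & mid]))
  expect_error(generate_bathymetry_and_mask(
    g, seed = 5, turbid_region = c(200, 201, 0, 1)), "turbid_region")
})

test_that("occurrence sampling follows the suitability surface", {
  w <- small_world()
  a <- sample_occurrences(w$surface, w$stack, 100, seed = 11)
  b <- sample_occurrences(w$surface, w$stack, 100, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_setequal(levels(a$era), c("past", "present"))
  expect_true(all(table(a$era) >= 1))

  # sampled cells always have positive suitability
  s <- true_suitability(w$surface, w$stack)
  big <- sample_occurrences(w$surface, w$stack, 2000, seed = 12)
  rc <- cell_of(w$grid, big$lon, big$lat)
  lin <- (rc$col - 1L) * w$grid$nrow + rc$row
  expect_true(all(s[lin] > 0))

  # uniform surface -> per-cell counts consistent with uniform multinomial
  su <- w$surface; su$t_curv <- 0; su$v_slope <- 0; su$intercept <- 0
  expect_true(sd(true_suitability(su, w$stack), na.rm = TRUE) < 1e-12)
  u <- sample_occurrences(su, w$stack, 2000, seed = 13)
  rcu <- cell_of(w$grid, u$lon, u$lat)
  linu <- (rcu$col - 1L) * w$grid$nrow + rcu$row
  cells <- which(w$stack$mask)
  counts <- tabulate(match(linu, cells), nbins = length(cells))
  p <- suppressWarnings(chisq.test(counts, p = rep(1, length(cells)) /
                                     length(cells))$p.value)
  expect_gt(p, 0.01)

  # empirical cell frequencies track normalized suitability (n = 1e4)
  big2 <- sample_occurrences(w$surface, w$stack, 1e4, seed = 14)
  rc2 <- cell_of(w$grid, big2$lon, big2$lat)
  lin2 <- (rc2$col - 1L) * w$grid$nrow + rc2$row
  emp <- tabulate(match(lin2, cells), nbins = length(cells)) / 1e4
  expected <- s[cells] / sum(s[cells])
  ord <- order(s[cells])
  expect_lt(max(abs(cumsum(emp[ord]) - cumsum(expected[ord]))), 0.02)

  dead <- w$surface; dead$intercept <- -Inf
  expect_error(sample_occurrences(dead, w$stack, 10), "degenerate")
})

test_that("MPA mask generation hits the requested coverage", {
  w <- small_world()
  m1 <- generate_mpa_mask(w$grid, seed = 1, coverage_fraction = 0.3,
                          mask = w$stack$mask)
  m2 <- generate_mpa_mask(w$grid, seed = 1, coverage_fraction = 0.3,
                          mask = w$stack$mask)
  expect_identical(m1$mask, m2$mask)
  expect_setequal(unique(as.vector(m1$mask)), c(0L, 1L))
  frac <- sum(m1$mask[w$stack$mask]) / sum(w$stack$mask)
  expect_gte(frac, 0.24)
  expect_lte(frac, 0.36)
  expect_error(generate_mpa_mask(w$grid, coverage_fraction = 1.2),
               "coverage_fraction")
})
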