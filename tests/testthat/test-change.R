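test_that("change categories reproduce the truth table", {
  expect_equal(as.character(change_category(FALSE, FALSE)), "Absence")
  expect_equal(as.character(change_category(TRUE, FALSE)), "Constriction")
  expect_equal(as.character(change_category(FALSE, TRUE)), "Expansion")
  expect_equal(as.character(change_category(TRUE, TRUE)), "Stability")
  expect_true(is.na(change_category(NA, TRUE)))
  m <- change_category(matrix(c(TRUE, FALSE), 1, 2),
                       matrix(c(FALSE, FALSE), 1, 2))
  expect_equal(dim(m), c(1L, 2L))
})

test_that("suitable area uses cosine-weighted spherical block areas", {
  # one suitable 0.2 degree block centred on the equator
  g <- grid_spec(0, -0.1, 0.2, nrow = 1, ncol = 1)
  sg <- suitability_grid(g, matrix(0.9, 1, 1))
  expect_equal(suitable_area(sg)$total_km2, (0.2 * 111.195)^2,
               tolerance = 1e-6)
  expect_equal((0.2 * 111.195)^2, 494.57, tolerance = 1e-2)
  # at 60 N the same block covers half the equatorial area
  g60 <- grid_spec(0, 59.9, 0.2, nrow = 1, ncol = 1)
  sg60 <- suitability_grid(g60, matrix(0.9, 1, 1))
  expect_equal(suitable_area(sg60)$total_km2,
               0.5 * suitable_area(sg)$total_km2, tolerance = 1e-9)
  # no suitable blocks -> zero; latitude bands partition the total
  sg0 <- suitability_grid(g, matrix(0.2, 1, 1))
  expect_equal(suitable_area(sg0)$total_km2, 0)
  w <- small_world()
  h <- matrix(runif(w$grid$nrow * w$grid$ncol), w$grid$nrow, w$grid$ncol)
  h[!w$stack$mask] <- NA
  sgw <- block_average(h, w$grid)
  sa <- suitable_area(sgw)
  expect_equal(sum(sa$by_latitude$area_km2), sa$total_km2)
})

test_that("trend percent matches the published-rounding examples", {
  expect_equal(round(trend_percent(14.40, 10.33), 2), -28.26)
  expect_lt(abs(trend_percent(14.40, 10.33) - (-28.25)), 0.15)
  expect_equal(round(trend_percent(6.61, 0.10), 2), -98.49)
  expect_lt(abs(trend_percent(6.61, 0.10) - (-98.45)), 0.15)
  expect_equal(trend_percent(3.3, 3.3), 0)
  expect_true(is.na(trend_percent(0, 5)))
})

test_that("weighted centroid averages latitudes by HSI over valid blocks", {
  g <- grid_spec(0, 33.9, 0.2, nrow = 11, ncol = 1)
  h <- matrix(NA_real_, 11, 1)
  h[1, 1] <- 0.2    # 34 N
  h[11, 1] <- 0.6   # 36 N
  sg <- suitability_grid(g, h)
  expect_equal(weighted_centroid(sg), 35.5)
  # uniform HSI -> arithmetic mean latitude; scale invariance
  hu <- matrix(0.3, 11, 1)
  sgu <- suitability_grid(g, hu)
  expect_equal(weighted_centroid(sgu), mean(cell_lats(g)))
  expect_equal(weighted_centroid(suitability_grid(g, h / 2)),
               weighted_centroid(sg))
  # centroid bounded by the latitudes of positive-HSI blocks
  expect_gte(weighted_centroid(sg), 34)
  expect_lte(weighted_centroid(sg), 36)
  expect_true(is.na(weighted_centroid(suitability_grid(g, h * 0))))
})

test_that("richness counts suitable species and flags misalignment", {
  g <- grid_spec(0, 0, 0.2, nrow = 2, ncol = 2)
  mk <- function(v) suitability_grid(g, matrix(v, 2, 2))
  a <- mk(c(0.5, 0.1, 0.9, NA))
  b <- mk(c(0.45, 0.1, 0.1, NA))
  r <- richness(list(a = a, b = b))
  expect_equal(as.vector(r$richness), c(2L, 0L, 1L, NA))
  g2 <- grid_spec(0, 0, 0.2, nrow = 2, ncol = 3)
  expect_error(richness(list(a, suitability_grid(g2, matrix(0.5, 2, 3)))),
               "alignment")
})

test_that("MPA overlap classes and protected fraction follow the rules", {
  g <- grid_spec(0, 0, 0.2, nrow = 2, ncol = 2)
  rich <- list(richness = matrix(c(2L, 0L, 1L, 0L), 2, 2),
               valid = matrix(TRUE, 2, 2), grid = g)
  mpa <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  ov <- mpa_overlap(rich, mpa)
  expect_equal(as.vector(ov$class),
               c("Protected", "Absence", "Unprotected", "Absence"))
  # equal-latitude blocks: fraction = 1 protected of 2 occupied
  expect_equal(ov$protected_fraction, 50, tolerance = 1e-9)
  # all suitable blocks inside the MPA -> 100%
  ov2 <- mpa_overlap(rich, matrix(1L, 2, 2))
  expect_equal(ov2$protected_fraction, 100)
  # any-of-16 rule with a native-resolution mask
  gn <- grid_spec(0, 0, 0.05, nrow = 8, ncol = 8)
  fine <- matrix(0L, 8, 8); fine[1, 1] <- 1L   # single fine cell
  ov3 <- mpa_overlap(rich, fine, mpa_grid = gn)
  expect_equal(ov3$class[1, 1], "Protected")
  expect_equal(ov3$class[1, 2], "Unprotected")
})

test_that("change summaries satisfy the conservation identities", {
  w <- small_world()
  set.seed(31)
  h1 <- matrix(runif(w$grid$nrow * w$grid$ncol), w$grid$nrow, w$grid$ncol)
  h2 <- pmin(pmax(h1 + rnorm(length(h1), -0.1, 0.2), 0), 1)
  h1[!w$stack$mask] <- NA; h2[!w$stack$mask] <- NA
  sg1 <- block_average(h1, w$grid)
  sg2 <- block_average(h2, w$grid)
  cs <- change_summary(sg1, sg2, species = "sp", scenario = "SSP5-8.5",
                       period = "2090s")
  ab <- cs$area_by_category_km2
  expect_equal(ab[["Stability"]] + ab[["Constriction"]],
               1e3 * cs$area_present, tolerance = 1e-6)
  expect_equal(ab[["Stability"]] + ab[["Expansion"]],
               1e3 * cs$area_future, tolerance = 1e-6)
  expect_equal(cs$trend,
               trend_percent(cs$area_present, cs$area_future))
  # centroid lies inside the latitude range of positive-HSI blocks
  lats <- lat_matrix(sg1$grid)[sg1$valid & sg1$hsi > 0]
  expect_gte(cs$centroid_present, min(lats))
  expect_lte(cs$centroid_present, max(lats))
})
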