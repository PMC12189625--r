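test_that("occurrence CSV loading assigns eras, drops out-of-bounds, validates", {
  g <- grid_spec(124, 32, 0.05, nrow = 20, ncol = 20)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,lon,lat,year",
               "sp1,124.1,32.1,1999",
               "sp1,124.2,32.2,2000",
               "sp1,150.0,32.2,2010",          # out of bounds
               "sp1,124.025,32.025,1980"),     # corner cell centre
             f)
  expect_message(occ <- load_occurrences(f, g), "outside the grid")
  expect_equal(nrow(occ), 3)
  expect_equal(as.character(occ$era), c("past", "present", "past"))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("species,lon,lat,year", empty)
  expect_equal(nrow(load_occurrences(empty, g)), 0)

  noyear <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,lon,lat", "sp1,124.1,32.1"), noyear)
  expect_error(load_occurrences(noyear, g), "missing column")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,lon,lat,year", "sp1,124.1,32.1,2001",
               "sp1,not-a-number,32.1,2001"), bad)
  expect_error(load_occurrences(bad, g), "line 2")

  # round trip
  out <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, out)
  back <- load_occurrences(out, g)
  expect_equal(as.data.frame(back), as.data.frame(occ), tolerance = 1e-6)
})

test_that("0.05 degree deduplication keeps first record per species/era cell", {
  df <- data.frame(
    species = c("a", "a", "a", "a", "b"),
    lon = c(124.01, 124.04, 124.06, 124.01, 124.01),  # rows 1+2 same cell
    lat = c(32.01, 32.02, 32.01, 32.01, 32.01),
    year = c(2001, 2005, 2004, 1990, 2010))           # row 4 other era
  occ <- occurrence_set(df)
  dd <- dedup_to_grid(occ)
  expect_true(attr(dd, "dedup"))
  expect_equal(nrow(dd), 4)                       # one dropped
  expect_true(2005 %in% df$year && !2005 %in% dd$year)  # first kept
  # adjacent cells both retained, other species and era retained
  expect_setequal(dd$year, c(2001, 2004, 1990, 2010))
  # idempotence
  expect_identical(as.data.frame(dedup_to_grid(dd)), as.data.frame(dd))
})

test_that("boundary points map to exactly one cell (half-open convention)", {
  g <- grid_spec(124, 32, 0.05, nrow = 10, ncol = 10)
  # interior cell boundary belongs to the cell to its north/east
  expect_equal(cell_of(g, 124.05, 32.0)$col, 2L)
  expect_equal(cell_of(g, 124.0, 32.05)$row, 2L)
  # outer north/east boundary closed
  expect_equal(cell_of(g, 124.5, 32.5), data.frame(row = 10L, col = 10L))
  expect_true(is.na(cell_of(g, 124.51, 32.1)$col))
  set.seed(1)
  lon <- 124 + 0.05 * sample(0:10, 50, replace = TRUE)
  lat <- 32 + 0.05 * sample(0:10, 50, replace = TRUE)
  rc <- cell_of(g, lon, lat)
  expect_true(all(rc$row >= 1 & rc$row <= 10 & rc$col >= 1 & rc$col <= 10))
})

test_that("stack CSV round-trips values, mask and grid", {
  w <- small_world()
  f <- withr::local_tempfile(fileext = ".csv")
  write_stack_csv(w$stack, f)
  back <- read_stack_csv(f)
  expect_true(sargassdm:::same_grid(back$grid, w$grid))
  expect_identical(back$mask, w$stack$mask)
  for (nm in names(w$stack$layers))
    expect_equal(back$layers[[nm]], w$stack$layers[[nm]], tolerance = 1e-6)
  expect_equal(back$depth, w$stack$depth, tolerance = 1e-6)
})

test_that("point extraction returns layer values in requested column order", {
  g <- grid_spec(0, 0, 0.05, nrow = 2, ncol = 2)
  layers <- list(ta = matrix(c(12, 2, 3, 4), 2, 2),
                 tb = matrix(c(5, 6, 7, 8), 2, 2))
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  st <- env_stack(g, layers, mask = mask)
  occ <- occurrence_set(data.frame(
    species = "x", lon = c(0.01, 0.06, 0.07), lat = c(0.01, 0.01, 0.07),
    year = 2001), dedup = TRUE)
  expect_message(d <- extract_at_points(st, occ, c("tb", "ta")), "1 record")
  expect_identical(colnames(d), c("tb", "ta"))
  expect_equal(d[1, ], c(tb = 5, ta = 12))
  expect_equal(attr(d, "dropped"), 1L)        # masked cell dropped
  allmasked <- occurrence_set(data.frame(
    species = "x", lon = 0.07, lat = 0.07, year = 2001), dedup = TRUE)
  expect_error(suppressMessages(extract_at_points(st, allmasked)),
               "empty design")
})

test_that("MPA masks round-trip through CSV and GeoJSON", {
  w <- small_world()
  mpa <- generate_mpa_mask(w$grid, seed = 3, coverage_fraction = 0.2,
                           mask = w$stack$mask)
  f1 <- withr::local_tempfile(fileext = ".csv")
  write_mpa_csv(mpa$mask, w$grid, f1)
  expect_identical(read_mpa_csv(f1, w$grid), mpa$mask)

  f2 <- withr::local_tempfile(fileext = ".geojson")
  write_mpa_geojson(mpa$polygons, f2)
  back <- read_mpa_geojson(f2, w$grid)
  expect_identical(back, mpa$mask)
})
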