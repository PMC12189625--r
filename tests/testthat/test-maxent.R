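# independent brute-force oracle: grid minimization of the penalized
# MaxEnt objective (used for <=2-feature toys)
oracle_objective <- function(lam, fp, fb, pen) {
  -mean(fp %*% lam) + log(sum(exp(fb %*% lam))) + sum(pen * abs(lam))
}
oracle_grid_min <- function(fp, fb, pen, lo = -3, hi = 3, step = 0.01) {
  grid <- seq(lo, hi, by = step)
  if (ncol(fp) == 1) {
    vals <- vapply(grid, function(a) oracle_objective(a, fp, fb, pen),
                   numeric(1))
    list(par = grid[which.min(vals)], value = min(vals))
  } else {
    best <- Inf; par <- NULL
    for (a in grid) {
      v <- vapply(grid, function(b)
        oracle_objective(c(a, b), fp, fb, pen), numeric(1))
      if (min(v) < best) { best <- min(v); par <- c(a, grid[which.min(v)]) }
    }
    list(par = par, value = best)
  }
}

test_that("feature expansion scales, knots and drops constants correctly", {
  bg <- cbind(x = c(0, 5, 10), y = c(2, 2, 2))
  expect_warning(fd <- make_feature_defs(bg, n_hinge_knots = 2), "constant")
  expect_identical(fd$vars, "x")
  f <- expand_features(fd, cbind(x = c(0, 10, 5), y = 0))
  expect_equal(f[, "linear.x"], c(0, 1, 0.5))          # endpoints scale to 0/1
  expect_equal(f[, "quadratic.x"], c(0, 1, 0.25))
  # at a knot both hinge features vanish: knot 1/3 of scaled range = x 10/3
  fk <- expand_features(fd, cbind(x = 10 / 3, y = 0))
  expect_equal(unname(fk[, grep("0.333", colnames(fk))]), c(0, 0))
  # all features within [0, 1] on background
  fb <- expand_features(fd, bg)
  expect_true(all(fb >= 0 & fb <= 1))
})

test_that("single binary feature recovers the closed-form weight ln 3", {
  fp <- matrix(c(rep(1, 15), rep(0, 5)), ncol = 1)   # presence mean 0.75
  fb <- matrix(rep(c(1, 0), each = 50), ncol = 1)
  m <- fit_maxent(fp, fb, beta_multiplier = 0)
  expect_equal(m$weights, log(3), tolerance = 1e-4, ignore_attr = TRUE)
  expect_equal(sum(predict(m, fb, type = "raw")), 1, tolerance = 1e-6)
})

test_that("penalty-dominated limit gives the uniform null model", {
  d <- world_designs(c("temp_ltmin", "vel_mean"), n_background = 300)
  fd <- make_feature_defs(d$background)
  fp <- expand_features(fd, d$presence)
  fb <- expand_features(fd, d$background)
  m <- fit_maxent(fp, fb, beta_multiplier = 1e6)
  expect_true(all(m$weights == 0))
  raw <- predict(m, fb, type = "raw")
  expect_equal(raw, rep(1 / nrow(fb), nrow(fb)), tolerance = 1e-12)
  expect_equal(predict(m, fb, type = "logistic"), rep(0.5, nrow(fb)),
               tolerance = 1e-12)
})

test_that("fits match the brute-force grid oracle on toy problems", {
  set.seed(21)
  # two-feature toy on 50 background cells
  fb <- cbind(a = runif(50), b = runif(50))
  fp <- cbind(a = runif(12, 0.4, 1), b = runif(12, 0, 0.6))
  m <- fit_maxent(fp, fb, beta_multiplier = 0.5)
  orc <- oracle_grid_min(fp, fb, m$penalties)
  fitted_obj <- oracle_objective(m$weights, fp, fb, m$penalties)
  expect_lte(fitted_obj, orc$value + 1e-3)
  expect_equal(m$weights, orc$par, tolerance = 0.05, ignore_attr = TRUE)
  # fitted objective never exceeds the grid minimum beyond tolerance
  expect_lte(fitted_obj, orc$value + 1e-6)
})

test_that("objective decreases monotonically and shrinkage is monotone in beta", {
  d <- world_designs(c("temp_ltmin", "vel_mean", "sal_mean"),
                     n_background = 500)
  l1 <- c()
  for (beta in c(0.5, 1, 2, 5, 10)) {
    m <- train_maxent(d$presence, d$background, beta_multiplier = beta)
    expect_true(all(diff(m$obj_trace) <= 1e-10))
    l1 <- c(l1, sum(abs(m$weights)))
  }
  expect_true(all(diff(l1) <= 1e-6))
})

test_that("prediction transforms are consistent and clamp novel values", {
  d <- world_designs(c("temp_ltmin", "vel_mean"), n_background = 400)
  m <- train_maxent(d$presence, d$background)
  raw <- predict(m, d$background, type = "raw")
  lgs <- predict(m, d$background, type = "logistic")
  cll <- predict(m, d$background, type = "cloglog")
  expect_equal(sum(raw), 1, tolerance = 1e-9)
  expect_true(all(lgs >= 0 & lgs <= 1) && all(cll >= 0 & cll <= 1))
  expect_true(all(diff(lgs[order(raw)]) >= 0))   # monotone transform
  novel <- d$background[1:3, , drop = FALSE]
  novel[1, 1] <- novel[1, 1] + 100
  expect_warning(predict(m, novel), "clamped")
  unfitted <- m; unfitted$fitted <- FALSE
  expect_error(predict(unfitted, d$background), "not fitted")
})

test_that("permutation contribution sums to 100 and respects symmetry", {
  d <- world_designs(c("temp_ltmin", "vel_mean"), n_background = 400)
  # duplicated variable entering symmetrically
  pres <- cbind(d$presence, dup = d$presence[, "temp_ltmin"])
  bg <- cbind(d$background, dup = d$background[, "temp_ltmin"])
  colnames(pres)[3] <- colnames(bg)[3] <- "temp_dup"
  m <- train_maxent(pres, bg)
  vc <- variable_contribution(m, pres, bg, n_permutations = 20, seed = 4)
  expect_equal(sum(vc), 100, tolerance = 1e-9)
  expect_equal(vc[["temp_ltmin"]], vc[["temp_dup"]], tolerance = 12)

  single <- train_maxent(d$presence[, "vel_mean", drop = FALSE],
                         d$background[, "vel_mean", drop = FALSE])
  expect_equal(variable_contribution(single, d$presence, d$background),
               c(vel_mean = 100))
})

test_that("response curves sweep the background range", {
  d <- world_designs(c("temp_ltmin", "vel_mean"), n_background = 400)
  m <- train_maxent(d$presence, d$background)
  rc <- response_curve(m, "temp_ltmin", n_points = 25)
  expect_equal(nrow(rc), 25)
  expect_equal(range(rc$value),
               range(d$background[, "temp_ltmin"]))
  expect_equal(nrow(response_curve(m, "temp_ltmin", n_points = 2)), 2)
  expect_error(response_curve(m, "nope"), "unknown variable")

  null <- train_maxent(d$presence, d$background, beta_multiplier = 1e6)
  rc0 <- response_curve(null, "vel_mean", n_points = 10)
  expect_equal(rc0$hsi, rep(0.5, 10), tolerance = 1e-12)
})

test_that("models serialize to JSON and reproduce predictions", {
  d <- world_designs(c("temp_ltmin", "vel_mean"), n_background = 300)
  m <- train_maxent(d$presence, d$background)
  f <- withr::local_tempfile(fileext = ".json")
  write_maxent_json(m, f)
  back <- read_maxent_json(f)
  expect_equal(predict(back, d$background, type = "logistic"),
               predict(m, d$background, type = "logistic"), tolerance = 1e-12)
  expect_equal(back$entropy, m$entropy)
})
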