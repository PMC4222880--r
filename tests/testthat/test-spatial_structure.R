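test_that("empirical variograms follow Matheron's estimator", {
  # two points 1 nm apart along transect, values 0 and 2
  e <- empirical_variogram(c(0, 0), c(0, 1), c(0, 2), lag_width = 2,
                           n_lags = 3)
  expect_equal(e$gamma[e$direction == "along" & e$lag == 1], 2)
  expect_equal(e$n_pairs[e$direction == "along" & e$lag == 1], 1)
  # constant field
  ec <- empirical_variogram(runif(20), runif(20), rep(5, 20), lag_width = 1,
                            n_lags = 2, angular_tol = 90)
  expect_true(all(ec$gamma[ec$n_pairs > 0] == 0))
  expect_error(empirical_variogram(1, 1, 1), "two points")
})

test_that("empirical variograms match a brute-force double loop", {
  set.seed(8)
  for (rep_ in 1:3) {
    n <- 60
    x <- runif(n, 0, 40); y <- runif(n, 0, 40); v <- rnorm(n)
    az <- sample(c(0, 30), 1)
    e <- empirical_variogram(x, y, v, lag_width = 3, n_lags = 10,
                             angular_tol = 15, azimuth = az)
    for (dir in c("along", "across")) {
      o <- oracle_variogram(x, y, v, dir, 3, 10, 15, az)
      sub <- e[e$direction == dir, ]
      expect_equal(sub$n_pairs, o$n_pairs)
      expect_equal(sub$gamma, o$gamma, tolerance = 1e-10)
    }
  }
})

test_that("gamma is invariant to constant shifts and pair order", {
  set.seed(9)
  x <- runif(30, 0, 20); y <- runif(30, 0, 20); v <- rnorm(30)
  e1 <- empirical_variogram(x, y, v, angular_tol = 90)
  e2 <- empirical_variogram(x, y, v + 100, angular_tol = 90)
  expect_equal(e1$gamma, e2$gamma, tolerance = 1e-9)
  perm <- sample(30)
  e3 <- empirical_variogram(x[perm], y[perm], v[perm], angular_tol = 90)
  expect_equal(e1$gamma, e3$gamma, tolerance = 1e-10)
})

test_that("yearly standardization yields mean 0, variance 1, idempotently", {
  set.seed(10)
  years <- rep(1:3, each = 40)
  v <- rnorm(120, mean = rep(c(0, 5, -2), each = 40),
             sd = rep(c(1, 4, 0.3), each = 40))
  s <- standardize_by_year(v, years)
  for (yr in 1:3) {
    expect_equal(mean(s[years == yr]), 0, tolerance = 1e-12)
    expect_equal(var(s[years == yr]), 1, tolerance = 1e-12)
  }
  expect_equal(standardize_by_year(s, years), s, tolerance = 1e-12)
  expect_error(standardize_by_year(rep(1, 10), rep(1, 10)), "zero variance")
})

test_that("model fitting recovers known parameters from exact curves", {
  m <- vgm_model(nugget = 0.1, sill = c(0.5, 0.4), range_along = c(4, 12),
                 range_across = c(8, 24))
  lag <- (1:25 - 0.5) * 2
  mk <- function(dir) {
    data.frame(direction = dir, lag = lag, dist_avg = lag,
               gamma = predict(m, lag, dir), n_pairs = 100)
  }
  f <- fit_variogram_model(mk("along"), mk("across"), n_structures = 2)
  expect_equal(coef(f), coef(m), tolerance = 0.01)
  # flat variogram collapses to pure nugget
  flat <- function(dir) data.frame(direction = dir, lag = lag,
                                   dist_avg = lag, gamma = 1, n_pairs = 50)
  f2 <- fit_variogram_model(flat("along"), flat("across"), n_structures = 1)
  expect_equal(f2$nugget, 1, tolerance = 1e-3)
  expect_lt(f2$structures$sill[1], 1e-3)
  expect_error(fit_variogram_model(mk("along")[1:2, ], mk("across")),
               "3 non-empty lags")
})

test_that("the mean variogram pools within-year pairs only", {
  set.seed(11)
  n <- 50
  x <- runif(n, 0, 30); y <- runif(n, 0, 30)
  v1 <- rnorm(n); v2 <- rnorm(n)
  # identical data every year: mean variogram equals the annual one
  mv <- mean_variogram(c(x, x), c(y, y), c(v1, v1), rep(1:2, each = n),
                       n_structures = 1, standardize = FALSE)
  ann <- empirical_variogram(x, y, v1)
  expect_equal(mv$empirical$gamma, ann$gamma, tolerance = 1e-12)
  expect_equal(mv$empirical$n_pairs, 2L * ann$n_pairs)
  # pooled gamma = sum(N_y * gamma_y) / sum(N_y), against per-year curves
  mv2 <- mean_variogram(c(x, x), c(y, y), c(v1, v2), rep(1:2, each = n),
                        n_structures = 1, standardize = FALSE)
  a1 <- empirical_variogram(x, y, v1); a2 <- empirical_variogram(x, y, v2)
  pooled <- (ifelse(a1$n_pairs > 0, a1$gamma * a1$n_pairs, 0) +
               ifelse(a2$n_pairs > 0, a2$gamma * a2$n_pairs, 0)) /
    pmax(a1$n_pairs + a2$n_pairs, 1)
  has <- (a1$n_pairs + a2$n_pairs) > 0
  expect_equal(mv2$empirical$gamma[has], pooled[has], tolerance = 1e-10)
  # cross-year pairs do not contribute: putting year 2 at the same
  # coordinates as year 1 with wildly different values must not change
  # year-1-only pair counts
  expect_equal(sum(mv2$empirical$n_pairs),
               2 * sum(a1$n_pairs[a1$n_pairs > 0]))
  expect_error(mean_variogram(x, y, v1, rep(1, n)), ">= 2 years")
})

test_that("standardized data give mean-variogram sills near one", {
  loc <- as.matrix(design_locations(survey_design())[, c("x", "y")])
  m <- vgm_model(nugget = 0.2, sill = 0.8, range_along = 10,
                 range_across = 14)
  z <- simulate_gaussian_field(loc, m, seed = 31, n_sims = 4)
  mv <- mean_variogram(rep(loc[, 1], 4), rep(loc[, 2], 4), as.vector(z),
                       rep(1:4, each = nrow(loc)), n_structures = 1)
  # pair-weighted semivariance beyond the range ~ sample variance = 1
  # (weighting by pairs avoids overweighting sparse distant classes,
  # which overshoot 1 in a finite domain)
  far <- mv$empirical$lag >= 14 & mv$empirical$n_pairs > 0
  expect_equal(weighted.mean(mv$empirical$gamma[far],
                             mv$empirical$n_pairs[far]), 1,
               tolerance = 0.15)
  expect_equal(total_sill(mv$model), 1, tolerance = 0.15)
})

test_that("simulation envelopes bracket the model and order their bounds", {
  loc <- as.matrix(design_locations(
    survey_design(n_transects = 5, transect_length = 20))[, c("x", "y")])
  m <- vgm_model(nugget = 0.2, sill = 0.8, range_along = 8,
                 range_across = 12)
  env <- variogram_envelope(m, loc, n_sim = 150, seed = 41, n_lags = 12,
                            standardize = FALSE)
  ok <- env$n_pairs > 0
  expect_true(all(env$lower[ok] <= env$upper[ok]))
  # interior lags should bracket the model curve
  for (dir in c("along", "across")) {
    sub <- env[env$direction == dir & env$n_pairs > 10 & env$lag < 16, ]
    gm <- predict(m, sub$lag, dir)
    expect_true(all(gm >= sub$lower & gm <= sub$upper))
  }
  # degenerate two-simulation envelope is still ordered
  env2 <- variogram_envelope(m, loc, n_sim = 2, seed = 42, n_lags = 8)
  ok2 <- env2$n_pairs > 0
  expect_true(all(env2$lower[ok2] <= env2$upper[ok2]))
  expect_identical(attr(env2, "n_sim"), 2)
})

test_that("the stability test flags only envelope excursions", {
  env <- data.frame(direction = rep(c("along", "across"), each = 5),
                    lag = rep((1:5 - 0.5) * 2, 2),
                    lower = 0.5, upper = 1.5, n_pairs = 10)
  class(env) <- c("variogram_envelope", "data.frame")
  mid <- data.frame(direction = rep(c("along", "across"), each = 5),
                    lag = rep((1:5 - 0.5) * 2, 2), gamma = 1, n_pairs = 8)
  class(mid) <- c("empirical_variogram", "data.frame")
  st <- test_annual_stability(mid, env)
  expect_true(st$stable)
  expect_equal(st$fraction_outside, 0)
  high <- transform(mid, gamma = 15)
  class(high) <- class(mid)
  expect_false(test_annual_stability(high, env)$stable)
  short <- mid[mid$direction == "along", ]
  class(short) <- class(mid)
  mismatch <- transform(short, lag = lag + 1)
  class(mismatch) <- class(mid)
  expect_error(test_annual_stability(mismatch, env), "lag grids")
})
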