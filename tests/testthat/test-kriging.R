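test_that("ordinary kriging interpolates exactly and matches the oracle", {
  set.seed(16)
  n <- 25
  x <- runif(n, 0, 30); y <- runif(n, 0, 30); v <- rnorm(n)
  m <- vgm_model(nugget = 0, sill = 1, range_along = 12, range_across = 12)
  # exactness at data locations, zero-nugget model
  at_data <- krige(x, y, v, m, data.frame(x = x, y = y),
                   neighbourhood_spec(1e6, 1e6, 1, n))
  expect_equal(at_data$prediction, v, tolerance = 1e-6)
  expect_true(all(at_data$kriging_variance >= 0))
  # unconstrained-neighbourhood agreement with the semivariance-form oracle
  nodes <- data.frame(x = runif(5, 5, 25), y = runif(5, 5, 25))
  km <- krige(x, y, v, m, nodes, neighbourhood_spec(1e6, 1e6, 1, n))
  for (g in 1:5) {
    o <- oracle_ok(x, y, v, m, nodes$x[g], nodes$y[g])
    expect_equal(km$prediction[g], o$prediction, tolerance = 1e-8)
    expect_equal(km$kriging_variance[g], o$variance, tolerance = 1e-8)
    expect_equal(sum(o$weights), 1, tolerance = 1e-10)
  }
})

test_that("the anisotropic search respects radii and neighbour counts", {
  # data on two transects 12 nm apart; node midway
  x <- rep(c(0, 12), each = 5); y <- rep(0:4, 2); v <- rnorm(10)
  m <- vgm_model(nugget = 0.1, sill = 1, range_along = 10)
  # across radius too small to reach either transect from x = 6 -> masked
  km1 <- krige(x, y, v, m, data.frame(x = 6, y = 2),
               neighbourhood_spec(radius_along = 10, radius_across = 2,
                                  min_neighbours = 1, max_neighbours = 10))
  expect_true(is.na(km1$prediction))
  expect_equal(km1$n_neighbours, 0)
  # wide across radius reaches both transects
  km2 <- krige(x, y, v, m, data.frame(x = 6, y = 2),
               neighbourhood_spec(radius_along = 10, radius_across = 30,
                                  min_neighbours = 4, max_neighbours = 6))
  expect_false(is.na(km2$prediction))
  expect_lte(km2$n_neighbours, 6)
  # prediction within data range when weights are non-negative is the
  # usual situation for interior nodes
  expect_true(km2$prediction > min(v) - 2 && km2$prediction < max(v) + 2)
  expect_error(neighbourhood_spec(min_neighbours = 5, max_neighbours = 2))
})

test_that("grids are masked to the sampled hull and design polygon", {
  x <- c(0, 10, 10, 0); y <- c(0, 0, 10, 10)
  g <- make_grid(x, y, resolution = 1)
  expect_equal(nrow(g), 11 * 11)
  poly <- cbind(c(0, 5, 5, 0), c(0, 0, 10, 10))
  g2 <- make_grid(x, y, resolution = 1, polygon = poly)
  expect_true(all(g2$x <= 5))
})

test_that("average and variability maps combine annual maps node-wise", {
  mk <- function(p) {
    out <- data.frame(x = 1:4, y = 1:4, prediction = p,
                      kriging_variance = 0, n_neighbours = 5)
    class(out) <- c("kriged_map", "data.frame")
    out
  }
  same <- average_variability_maps(list(mk(1:4), mk(1:4)))
  expect_equal(same$sd, rep(0, 4))
  two <- average_variability_maps(list(mk(c(1, 2, 3, 4)),
                                       mk(c(3, 4, 5, 6))))
  expect_equal(two$mean, c(2, 3, 4, 5))
  expect_equal(two$sd, rep(sqrt(2), 4))
  expect_error(average_variability_maps(list(mk(1:4))), ">= 2")
  bad <- mk(1:4); bad$x <- bad$x + 1
  expect_error(average_variability_maps(list(mk(1:4), bad)), "same grid")
})

test_that("area classification applies the median splits and tie rule", {
  av <- data.frame(x = 1:2, y = 1:2, mean = c(1, 4), sd = c(3, 1))
  cl <- classify_areas(av)
  expect_equal(as.character(cl$category), c("occasional", "recurrent"))
  # all-identical maps: sd >= median(sd) everywhere -> all occasional
  av0 <- data.frame(x = 1:3, y = 1:3, mean = c(2, 2, 2), sd = c(0, 0, 0))
  expect_true(all(classify_areas(av0)$category == "occasional"))
  # continuous sd values: occasional fraction ~ half by the median split
  set.seed(17)
  avc <- data.frame(x = 1:400, y = 1:400, mean = rnorm(400),
                    sd = runif(400))
  cc <- classify_areas(avc)
  expect_equal(mean(cc$category == "occasional"), 0.5, tolerance = 0.01)
  # category counts cover every valid node
  expect_equal(sum(table(cc$category)), 400)
})
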