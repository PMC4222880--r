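test_that("centre of gravity is the biomass-weighted mean location", {
  expect_equal(centre_of_gravity(c(0, 2), c(0, 0)), c(x = 1, y = 0))
  expect_equal(centre_of_gravity(c(0, 4), c(0, 0), c(1, 3)), c(x = 3, y = 0))
  expect_equal(centre_of_gravity(5, 7), c(x = 5, y = 7))
  expect_error(centre_of_gravity(c(0, 1), c(0, 0), c(0, 0)), "positive")
})

test_that("inertia measures weighted spread and decomposes on axes", {
  g <- inertia(c(0, 2), c(0, 0))
  expect_equal(g$inertia, 1)
  expect_equal(sum(g$axis_var), g$inertia, tolerance = 1e-9)
  # an inertia of 1152 nm^2 corresponds to an RMS distance of ~34 nm
  expect_equal(sqrt(1152), 34, tolerance = 0.01)
  g0 <- inertia(c(3, 3, 3), c(1, 1, 1), c(2, 1, 4))
  expect_equal(g0$inertia, 0)
  # rigid rotation: inertia invariant, CG equivariant
  set.seed(12)
  x <- runif(30); y <- runif(30); w <- rexp(30)
  th <- 0.7
  xr <- x * cos(th) - y * sin(th); yr <- x * sin(th) + y * cos(th)
  a <- inertia(x, y, w); b <- inertia(xr, yr, w)
  expect_equal(b$inertia, a$inertia, tolerance = 1e-10)
  expect_equal(unname(b$cg["x"]),
               unname(a$cg["x"] * cos(th) - a$cg["y"] * sin(th)),
               tolerance = 1e-10)
  expect_equal(g$ellipse$a, sqrt(g$axis_var[1]))
})

test_that("patch identification honours the anisotropic thresholds", {
  # all points near the richest -> one patch
  p1 <- identify_patches(c(0, 1, 2), c(0, 1, 2), c(5, 1, 2), 6, 24)
  expect_equal(nrow(p1$patches), 1)
  # two equal clusters 100 nm apart -> two patches with equal shares
  x <- c(0, 1, 100, 101); y <- c(0, 0, 0, 0)
  p2 <- identify_patches(x, y, c(3, 2, 3, 2), 6, 24)
  expect_equal(nrow(p2$patches), 2)
  expect_equal(sort(p2$patches$biomass_share), c(0.5, 0.5))
  # anisotropy: 10 nm along (azimuth 0 -> y) exceeds 6-nm threshold,
  # 10 nm across stays within the 24-nm threshold
  pa <- identify_patches(c(0, 0), c(0, 10), c(2, 1), 6, 24)
  expect_equal(nrow(pa$patches), 2)
  pc <- identify_patches(c(0, 10), c(0, 0), c(2, 1), 6, 24)
  expect_equal(nrow(pc$patches), 1)
  expect_error(identify_patches(c(0, 1), c(0, 0), c(0, 0), 6, 24),
               "no presence")
})

test_that("patch partition closes biomass accounting", {
  set.seed(13)
  x <- runif(60, 0, 90); y <- runif(60, 0, 30)
  v <- ifelse(runif(60) < 0.3, 0, rexp(60))
  ps <- identify_patches(x, y, v, 6, 24)
  expect_equal(sort(ps$assignment$index), which(v > 0))
  expect_equal(sum(ps$patches$biomass), sum(v[v > 0]), tolerance = 1e-10)
  expect_equal(sum(ps$patches$biomass_share), 1, tolerance = 1e-10)
  # every presence sample in exactly one patch
  expect_false(anyDuplicated(ps$assignment$index) > 0)
})

test_that("patch assignments match a step-by-step oracle", {
  set.seed(14)
  for (rep_ in 1:6) {
    n <- sample(5:12, 1)
    x <- runif(n, 0, 40); y <- runif(n, 0, 40)
    v <- round(rexp(n), 3)
    v[sample(n, 1)] <- 0
    if (all(v == 0)) v[1] <- 1
    ps <- identify_patches(x, y, v, 6, 24)
    o <- oracle_patches(x, y, v, 6, 24)
    expect_equal(ps$assignment$index, o$order)
    expect_equal(ps$assignment$patch_id, o$patch_id)
  }
})

test_that("EOF identities hold: rank, variance shares, reconstruction", {
  set.seed(15)
  base <- rexp(12)
  two <- rbind(base, base)          # two identical years -> rank 1
  e1 <- eof(two, "relative")
  expect_equal(e1$pct_variance[1], 100, tolerance = 1e-8)
  m <- matrix(rexp(5 * 20), 5, 20)
  e <- eof(m, "relative")
  expect_equal(sum(e$pct_variance), 100, tolerance = 1e-8)
  expect_true(all(diff(e$eigenvalues) <= 1e-9))
  recon <- e$year_scores %*% t(e$point_loadings)
  expect_lt(norm(recon - e$centred, "F") / norm(e$centred, "F"), 1e-8)
  expect_error(eof(m[, 1, drop = FALSE]), ">= 2")
  m[1, 1] <- NA
  expect_error(eof(m), "missing")
})

test_that("pointwise CV tracks relocation of relative biomass", {
  # identical shares every year -> CV 0
  m0 <- rbind(c(0.2, 0.8), c(0.2, 0.8))
  expect_equal(pointwise_cv(m0), c(0, 0))
  # relative values (0.25, 0.75) across two years: CV = sqrt(2)/2
  m1 <- rbind(c(0.25, 0.75), c(0.75, 0.25))
  expect_equal(pointwise_cv(m1), rep(sqrt(2) / 2, 2), tolerance = 1e-12)
  # never-occupied location flagged NA
  m2 <- rbind(c(1, 0), c(1, 0))
  expect_true(is.na(pointwise_cv(m2)[2]))
  expect_error(pointwise_cv(rbind(c(0.5, 0.4), c(0.5, 0.5))), "sum to 1")
})
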