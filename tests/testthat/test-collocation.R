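circle <- function(cx, cy, r) list(centre = c(cx, cy), a = r, b = r,
                                   angle = 0)

test_that("ellipse overlap hits its endpoint and nesting values", {
  e <- circle(0, 0, 1)
  expect_equal(ellipse_overlap(e, e), 1, tolerance = 1e-6)
  expect_equal(ellipse_overlap(e, circle(10, 0, 1)), 0)
  expect_equal(ellipse_overlap(e, circle(0, 0, 2)), 0.25, tolerance = 0.01)
  # symmetry, including for genuinely anisotropic ellipses
  e1 <- list(centre = c(1, 2), a = 4, b = 1.5, angle = 0.6)
  e2 <- list(centre = c(3, 1), a = 2.5, b = 1, angle = -0.3)
  expect_equal(ellipse_overlap(e1, e2), ellipse_overlap(e2, e1),
               tolerance = 1e-9)
  expect_true(ellipse_overlap(e1, e2) > 0 && ellipse_overlap(e1, e2) < 1)
  # degenerate ellipses
  pt <- list(centre = c(0, 0), a = 0, b = 0, angle = 0)
  expect_equal(ellipse_overlap(pt, e), 0)
  expect_equal(ellipse_overlap(pt, pt), 1)
})

test_that("patch-union overlap follows inclusion-exclusion arithmetic", {
  common <- data.frame(cg_x = 0, cg_y = 0, a = 1, b = 1, angle = 0)
  extra <- data.frame(cg_x = 10, cg_y = 0, a = 1, b = 1, angle = 0)
  expect_equal(patch_overlap(common, common), 1)
  expect_equal(patch_overlap(common, extra), 0)
  # one shared patch of area A plus one disjoint patch of area A -> 1/2
  expect_equal(patch_overlap(rbind(common, extra), common), 0.5,
               tolerance = 0.01)
})

test_that("local indices obey their endpoint identities", {
  expect_equal(cooccurrence_index(c(1, 1, 0), c(0, 1, 1)), 1 / 3)
  expect_equal(cooccurrence_index(c(1, 2), c(3, 1)), 1)
  expect_equal(cooccurrence_index(c(1, 0), c(0, 2)), 0)
  expect_error(cooccurrence_index(c(0, 0), c(0, 0)), "absent")

  zi <- c(2, 0, 1, 5)
  expect_equal(local_index_of_collocation(zi, 3.7 * zi), 1,
               tolerance = 1e-12)
  expect_equal(local_index_of_collocation(c(1, 0), c(0, 1)), 0)
  expect_equal(local_index_of_collocation(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(local_index_of_collocation(zi, rep(0, 4)), "absent")
})

test_that("LIC is a rescale-invariant cosine bounded by one", {
  set.seed(18)
  for (rep_ in 1:10) {
    zi <- rexp(30) * rbinom(30, 1, 0.7)
    zj <- rexp(30) * rbinom(30, 1, 0.7)
    if (sum(zi) == 0 || sum(zj) == 0) next
    l <- local_index_of_collocation(zi, zj)
    expect_lte(l, 1 + 1e-12)
    expect_gte(l, 0)
    expect_equal(local_index_of_collocation(5 * zi, 0.3 * zj), l,
                 tolerance = 1e-12)
  }
})

test_that("dominance is bounded, antisymmetric and NA at double absences", {
  zi <- c(3, 0, 2, 0); zj <- c(0, 4, 2, 0)
  d <- dominance_index(zi, zj)
  expect_equal(d[1:3], c(1, -1, 0))
  expect_true(is.na(d[4]))
  expect_equal(dominance_index(zj, zi)[1:3], -d[1:3])
  set.seed(19)
  a <- rexp(50) * rbinom(50, 1, 0.6); b <- rexp(50) * rbinom(50, 1, 0.6)
  dd <- dominance_index(a, b)
  expect_true(all(abs(dd[!is.na(dd)]) <= 1))
})

test_that("randomization test is calibrated, powerful and bounded", {
  set.seed(20)
  # power: identical heterogeneous fields give the smallest attainable p
  zi <- rexp(80)^2
  r <- randomization_test(zi, zi, "lic", n_resamples = 999, seed = 1)
  expect_lte(r$p_value, 0.01)
  expect_equal(r$p_value, 1 / 1000, tolerance = 1e-12)
  # p always in (0, 1]
  zj <- rexp(80)^2
  r2 <- randomization_test(zi, zj, "lic", n_resamples = 199, seed = 2)
  expect_gt(r2$p_value, 0)
  expect_lte(r2$p_value, 1)
  # determinism given seed
  r3 <- randomization_test(zi, zj, "lic", n_resamples = 199, seed = 2)
  expect_identical(r2$p_value, r3$p_value)
  # null calibration: independent fields -> roughly uniform p
  ps <- vapply(1:60, function(k) {
    a <- rexp(40); b <- rexp(40)
    randomization_test(a, b, "lic", n_resamples = 199, seed = k)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  expect_error(randomization_test(zi, zj, n_resamples = 10), ">= 99")
})

test_that("collocation tables assemble all indices per year", {
  ds <- make_toy_dataset()
  tab <- suppressWarnings(
    collocation_table(ds, "anchovy", "sardine", n_resamples = 199,
                      seed = 3))
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$global_overlap >= 0 & tab$global_overlap <= 1,
                  na.rm = TRUE))
  expect_true(all(tab$lic >= 0 & tab$lic <= 1, na.rm = TRUE))
  expect_true(all(tab$p_lic > 0 & tab$p_lic <= 1, na.rm = TRUE))
})
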