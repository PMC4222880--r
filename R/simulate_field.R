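#' Simulate Gaussian random fields by the turning-bands method
#'
#' Generates zero-mean stationary Gaussian fields at arbitrary planar
#' locations whose theoretical variogram is a given nested spherical model.
#' Each spherical component is simulated by turning bands: one-dimensional
#' moving-average processes are generated on lines through the origin and
#' summed. The line process uses the exact one-dimensional equivalent of
#' the spherical covariance (a moving average of white noise with a linear
#' ramp kernel over the component range), so the band covariance is exact
#' and the only approximation is the finite number of line directions.
#' Line directions are a Fibonacci lattice on the sphere, rotated by a
#' seeded random rotation; the planar locations live on the equatorial
#' plane. Geometric anisotropy is handled by scaling coordinates by the
#' directional ranges. The nugget is added as independent Gaussian noise.
#'
#' @param locations Two-column matrix or data frame of planar coordinates
#'   (nm).
#' @param model A [vgm_model()].
#' @param seed Integer seed; the result is a deterministic function of
#'   (locations, model, seed, n_bands, n_sims).
#' @param n_bands Number of turning-band lines.
#' @param n_sims Number of independent fields to draw.
#' @param azimuth Along-transect direction (degrees clockwise from north)
#'   defining the anisotropy axes of `model`.
#' @return A numeric matrix, `nrow(locations)` x `n_sims`.
#' @export
#' @examples
#' pts <- cbind(runif(50, 0, 30), runif(50, 0, 30))
#' z <- simulate_gaussian_field(pts, vgm_model(sill = 1, range_along = 10),
#'                              seed = 1)
simulate_gaussian_field <- function(locations, model, seed = NULL,
                                    n_bands = 180, n_sims = 1, azimuth = 0) {
  locations <- as.matrix(locations)
  if (nrow(locations) < 1) stopf("need at least one location")
  if (n_bands < 1) stopf("n_bands must be >= 1")
  if (!inherits(model, "vgm_model")) stopf("model must be a vgm_model")
  with_seed(seed, {
    n <- nrow(locations)
    z <- matrix(0, n, n_sims)
    aa <- along_across(locations[, 1], locations[, 2], azimuth)
    s <- model$structures
    for (i in seq_len(nrow(s))) {
      if (s$sill[i] <= 0) next
      sx <- aa[, "along"] / s$range_along[i]
      sy <- aa[, "across"] / s$range_across[i]
      z <- z + tb_component(sx, sy, s$sill[i], n_bands, n_sims)
    }
    if (model$nugget > 0) {
      z <- z + sqrt(model$nugget) * matrix(stats::rnorm(n * n_sims), n, n_sims)
    }
    z
  })
}

# One isotropic unit-range spherical component at scaled coordinates.
# Band process: X(t) = integral of (t-u) dW(u) over |t-u| <= 1/2, which has
# covariance c1(h) = (1 - 3h + 2h^3)/12 for h <= 1 -- the exact 1-D turning
# bands equivalent of the 3-D spherical covariance. Implemented with a
# discretised white-noise line and cumulative sums, then averaged over
# sphere directions.
tb_component <- function(sx, sy, sill, n_bands, n_sims) {
  n <- length(sx)
  dirs <- fibonacci_sphere(n_bands)
  # seeded random rotation so the lattice orientation is not special
  rot <- random_rotation()
  dirs <- dirs %*% t(rot)
  delta <- 1 / 50          # noise spacing in range units; kernel spans 50 cells
  scale <- sqrt(12 * sill) # raw MA variance is 1/12
  z <- matrix(0, n, n_sims)
  for (k in seq_len(n_bands)) {
    t_i <- dirs[k, 1] * sx + dirs[k, 2] * sy
    t0 <- min(t_i) - 0.5 - delta
    m <- ceiling((max(t_i) + 0.5 - t0) / delta) + 2
    u <- t0 + delta * seq_len(m)
    eps <- matrix(stats::rnorm(m * n_sims), m, n_sims)
    s1 <- apply(eps, 2, cumsum)
    s2 <- apply(u * eps, 2, cumsum)
    # window of noise cells within kernel support (t - 1/2, t + 1/2]
    a <- findInterval(t_i - 0.5, u)        # last index <= t - 1/2 (excluded)
    b <- findInterval(t_i + 0.5, u)        # last index <= t + 1/2 (included)
    s1a <- rbind(0, s1)[a + 1L, , drop = FALSE]
    s1b <- rbind(0, s1)[b + 1L, , drop = FALSE]
    s2a <- rbind(0, s2)[a + 1L, , drop = FALSE]
    s2b <- rbind(0, s2)[b + 1L, , drop = FALSE]
    z <- z + sqrt(delta) * (t_i * (s1b - s1a) - (s2b - s2a))
  }
  scale / sqrt(n_bands) * z
}

# Near-uniform directions on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  cz <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - cz^2))
  cbind(r * cos(phi), r * sin(phi), cz)
}

# Uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 3] <- -q[, 3]
  q
}
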