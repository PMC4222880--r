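# Bidirectional empirical variography, automatic model fitting, the
# multi-year mean variogram, and the simulation-envelope stability test.

# Classify all point pairs (i < j) into lag/direction classes. Directions
# are transect-relative: "along" keeps pairs whose separation vector lies
# within `angular_tol` degrees of the transect azimuth (mod 180), "across"
# within `angular_tol` of the perpendicular. Returns per-direction pair
# indices and lag class (1..n_lags); pairs beyond the last lag or outside
# both angular classes are dropped.
vgm_pairs <- function(x, y, azimuth = 0, lag_width = 2, n_lags = 25,
                      angular_tol = 15) {
  n <- length(x)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  aa <- along_across(x, y, azimuth)
  da <- aa[i, "along"] - aa[j, "along"]
  dc <- aa[i, "across"] - aa[j, "across"]
  d <- sqrt(da^2 + dc^2)
  lag <- floor(d / lag_width) + 1L
  keep <- d > 0 & lag <= n_lags
  phi <- atan2(abs(dc), abs(da))          # 0 = along axis, pi/2 = across axis
  tol <- angular_tol * pi / 180
  out <- list()
  for (dir in c("along", "across")) {
    ang_ok <- if (dir == "along") phi <= tol else (pi / 2 - phi) <= tol
    k <- keep & ang_ok
    out[[dir]] <- list(i = i[k], j = j[k], lag = lag[k], dist = d[k])
  }
  attr(out, "lag_width") <- lag_width
  attr(out, "n_lags") <- n_lags
  out
}

# gamma per lag for one direction given precomputed pairs; values may be a
# matrix (points x sims), in which case a lags x sims matrix is returned.
gamma_from_pairs <- function(pairs, values, n_lags) {
  if (is.matrix(values)) {
    d2 <- (values[pairs$i, , drop = FALSE] - values[pairs$j, , drop = FALSE])^2
    cnt <- tabulate(pairs$lag, n_lags)
    out <- matrix(NA_real_, n_lags, ncol(values))
    if (length(pairs$lag)) {
      agg <- rowsum(d2, pairs$lag, reorder = TRUE)
      lag_ids <- as.integer(rownames(agg))
      out[lag_ids, ] <- agg / (2 * cnt[lag_ids])
    }
    list(gamma = out, n_pairs = cnt)
  } else {
    d2 <- (values[pairs$i] - values[pairs$j])^2
    cnt <- tabulate(pairs$lag, n_lags)
    s <- rep(NA_real_, n_lags)
    dsum <- rep(NA_real_, n_lags)
    if (length(d2)) {
      agg <- rowsum(cbind(d2, pairs$dist), pairs$lag, reorder = TRUE)
      ids <- as.integer(rownames(agg))
      s[ids] <- agg[, 1]
      dsum[ids] <- agg[, 2]
    }
    list(gamma = s / (2 * cnt), n_pairs = cnt, dist_avg = dsum / cnt)
  }
}

#' Bidirectional empirical variogram
#'
#' Matheron's estimator \eqn{\gamma(h) = \frac{1}{2N(h)} \sum (z_i - z_j)^2}
#' over pairs whose separation vector falls in the requested lag and
#' direction class. Directions are transect-relative: pairs within
#' `angular_tol` degrees of the transect azimuth count as "along", within
#' `angular_tol` of its perpendicular as "across". Each unordered pair is
#' counted once. Lags with no pairs are reported with `n_pairs = 0` and
#' `gamma = NA` rather than dropped.
#'
#' @param x,y Planar coordinates (nm).
#' @param values Values at the points (typically log-biomass).
#' @param direction `"along"`, `"across"` or `"both"`.
#' @param lag_width Lag class width (nm). The default 2 nm suits 1-nm
#'   along-transect sampling with 12-nm transect spacing.
#' @param n_lags Number of lag classes; the default caps the maximum lag
#'   at 50 nm.
#' @param angular_tol Half-width of the angular class (degrees).
#' @param azimuth Along-transect direction (degrees clockwise from north).
#' @return A data frame of class `empirical_variogram` with columns
#'   `direction`, `lag` (class centre, nm), `dist_avg` (mean pair distance
#'   in the class, the abscissa used for model fitting), `gamma`,
#'   `n_pairs`.
#' @export
empirical_variogram <- function(x, y, values,
                                direction = c("both", "along", "across"),
                                lag_width = 2, n_lags = 25, angular_tol = 15,
                                azimuth = 0) {
  direction <- match.arg(direction)
  if (length(x) < 2) stopf("need at least two points")
  if (lag_width <= 0) stopf("lag_width must be positive")
  pairs <- vgm_pairs(x, y, azimuth, lag_width, n_lags, angular_tol)
  dirs <- if (direction == "both") c("along", "across") else direction
  out <- do.call(rbind, lapply(dirs, function(dir) {
    g <- gamma_from_pairs(pairs[[dir]], values, n_lags)
    data.frame(direction = dir, lag = (seq_len(n_lags) - 0.5) * lag_width,
               dist_avg = g$dist_avg, gamma = g$gamma, n_pairs = g$n_pairs)
  }))
  rownames(out) <- NULL
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

#' @export
plot.empirical_variogram <- function(x, model = NULL, ...) {
  dirs <- unique(x$direction)
  graphics::plot(x$lag, x$gamma, type = "n", xlab = "lag (nm)",
                 ylab = expression(gamma(h)), ...)
  for (k in seq_along(dirs)) {
    sub <- x[x$direction == dirs[k] & x$n_pairs > 0, ]
    graphics::points(sub$lag, sub$gamma, pch = k)
    if (!is.null(model)) {
      h <- seq(0, max(x$lag), length.out = 100)
      graphics::lines(h, predict(model, h, dirs[k]), lty = k)
    }
  }
  graphics::legend("bottomright", legend = dirs, pch = seq_along(dirs),
                   bty = "n")
  invisible(x)
}

#' Fit a nested anisotropic spherical model to directional variograms
#'
#' Weighted least squares (weights = pair counts) joint fit of a nugget
#' plus `n_structures` spherical components to the along- and
#' across-transect empirical variograms. Sills are shared between
#' directions; ranges are direction-specific (geometric anisotropy).
#' Several deterministic starting points are tried and the best local
#' optimum kept.
#'
#' @param emp_along,emp_across [empirical_variogram()] data frames for the
#'   two directions (a single data frame containing both directions may be
#'   passed as `emp_along`).
#' @param n_structures 1 or 2 spherical components.
#' @return A [vgm_model()] with attributes `objective` (weighted SSE) and
#'   `convergence`.
#' @export
fit_variogram_model <- function(emp_along, emp_across = NULL,
                                n_structures = 1) {
  if (is.null(emp_across)) {
    emp_across <- emp_along[emp_along$direction == "across", ]
    emp_along <- emp_along[emp_along$direction == "along", ]
  }
  if (!n_structures %in% 1:2) stopf("n_structures must be 1 or 2")
  ok_a <- emp_along$n_pairs > 0 & is.finite(emp_along$gamma)
  ok_c <- emp_across$n_pairs > 0 & is.finite(emp_across$gamma)
  if (sum(ok_a) < 3 || sum(ok_c) < 3) {
    stopf("need >= 3 non-empty lags in each direction")
  }
  # fit against the mean pair distance per lag class when available -- on
  # gridded samplings in-class distances are asymmetric about the centre
  lag_of <- function(emp, ok) {
    if (!is.null(emp$dist_avg) && all(is.finite(emp$dist_avg[ok]))) {
      emp$dist_avg[ok]
    } else emp$lag[ok]
  }
  ha <- lag_of(emp_along, ok_a); ga <- emp_along$gamma[ok_a]
  wa <- emp_along$n_pairs[ok_a]
  hc <- lag_of(emp_across, ok_c); gc <- emp_across$gamma[ok_c]
  wc <- emp_across$n_pairs[ok_c]
  hmax <- max(ha, hc)
  gtop <- max(ga, gc)

  k <- n_structures
  # parameter vector: nugget, sill[1..k], range_along[1..k], range_across[1..k]
  obj <- function(p) {
    m <- vgm_model(nugget = p[1], sill = p[2:(1 + k)],
                   range_along = p[(2 + k):(1 + 2 * k)],
                   range_across = p[(2 + 2 * k):(1 + 3 * k)])
    sum(wa * (ga - predict(m, ha, "along"))^2) +
      sum(wc * (gc - predict(m, hc, "across"))^2)
  }
  sill_mean <- max(mean(c(ga, gc)), 1e-8)
  starts <- list()
  range_grid <- if (k == 1) list(c(0.25), c(0.5), c(0.9)) else
    list(c(0.1, 0.5), c(0.2, 0.8), c(0.05, 0.3))
  for (rg in range_grid) {
    for (nug_frac in c(0.05, 0.3)) {
      starts[[length(starts) + 1]] <-
        c(nug_frac * sill_mean, rep((1 - nug_frac) * sill_mean / k, k),
          rg * hmax, rg * hmax)
    }
  }
  lower <- c(0, rep(0, k), rep(hmax * 1e-3, 2 * k))
  upper <- c(2 * gtop, rep(3 * gtop, k), rep(4 * hmax, 2 * k))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stopf("variogram model fit failed from every start")
  p <- best$par
  m <- vgm_model(nugget = p[1], sill = p[2:(1 + k)],
                 range_along = p[(2 + k):(1 + 2 * k)],
                 range_across = p[(2 + 2 * k):(1 + 3 * k)])
  attr(m, "objective") <- best$value
  attr(m, "convergence") <- best$convergence
  m
}

#' Standardize values year by year
#'
#' Subtracts each year's mean and divides by each year's standard
#' deviation, so every year contributes on the same scale (mean 0,
#' variance 1) to the mean variogram.
#'
#' @param values Numeric vector.
#' @param years Year label per value.
#' @return Standardized values in the original order.
#' @export
standardize_by_year <- function(values, years) {
  out <- numeric(length(values))
  for (yr in unique(years)) {
    idx <- years == yr
    s <- stats::sd(values[idx])
    if (!is.finite(s) || s == 0) {
      stopf("year %s has zero variance; cannot standardize", yr)
    }
    out[idx] <- (values[idx] - mean(values[idx])) / s
  }
  out
}

#' Multi-year mean variogram
#'
#' Pools pairs across years, a pair being retained only if both points
#' belong to the same year: the pooled semivariance per lag is the
#' pair-count-weighted average of the annual semivariances. Input values
#' are standardized per year first (see [standardize_by_year()]) unless
#' `standardize = FALSE`. The pooled curves are then fitted with
#' [fit_variogram_model()].
#'
#' @param x,y Planar coordinates (nm), all years stacked.
#' @param values Log-biomass values.
#' @param years Year label per point.
#' @param n_structures Passed to [fit_variogram_model()].
#' @param standardize Standardize per year before pooling.
#' @inheritParams empirical_variogram
#' @return A list of class `mean_variogram` with `empirical` (both
#'   directions) and `model`.
#' @export
mean_variogram <- function(x, y, values, years, lag_width = 2, n_lags = 25,
                           angular_tol = 15, azimuth = 0, n_structures = 2,
                           standardize = TRUE) {
  yrs <- unique(years)
  if (length(yrs) < 2) stopf("mean variogram needs >= 2 years")
  if (standardize) values <- standardize_by_year(values, years)
  sums <- list(along = numeric(n_lags), across = numeric(n_lags))
  dsums <- list(along = numeric(n_lags), across = numeric(n_lags))
  cnts <- list(along = integer(n_lags), across = integer(n_lags))
  for (yr in yrs) {
    idx <- years == yr
    pairs <- vgm_pairs(x[idx], y[idx], azimuth, lag_width, n_lags,
                       angular_tol)
    for (dir in c("along", "across")) {
      g <- gamma_from_pairs(pairs[[dir]], values[idx], n_lags)
      has <- g$n_pairs > 0
      sums[[dir]][has] <- sums[[dir]][has] +
        g$gamma[has] * g$n_pairs[has]
      dsums[[dir]][has] <- dsums[[dir]][has] +
        g$dist_avg[has] * g$n_pairs[has]
      cnts[[dir]] <- cnts[[dir]] + g$n_pairs
    }
  }
  emp <- do.call(rbind, lapply(c("along", "across"), function(dir) {
    has <- cnts[[dir]] > 0
    data.frame(direction = dir, lag = (seq_len(n_lags) - 0.5) * lag_width,
               dist_avg = ifelse(has, dsums[[dir]] / cnts[[dir]], NA),
               gamma = ifelse(has, sums[[dir]] / cnts[[dir]], NA),
               n_pairs = cnts[[dir]])
  }))
  class(emp) <- c("empirical_variogram", "data.frame")
  model <- fit_variogram_model(emp, n_structures = n_structures)
  structure(list(empirical = emp, model = model), class = "mean_variogram")
}

#' @export
print.mean_variogram <- function(x, ...) {
  cat("Mean variogram (within-year pairs pooled over years)\n")
  print(x$model)
  invisible(x)
}

#' Simulation envelope of the variogram under a fitted model
#'
#' Simulates `n_sim` Gaussian random fields from `model` at the sampling
#' locations (turning bands), computes the bidirectional empirical
#' variogram of each, and returns pointwise 2.5% and 97.5% quantiles per
#' lag. By default each simulated field is standardized (z-scored) before
#' its variogram is computed, matching the treatment of annually
#' standardized survey data.
#'
#' @param model A [vgm_model()], typically the fitted mean-variogram model.
#' @param locations Two-column matrix of one year's sampling locations.
#' @param n_sim Number of simulated fields (>= 100 for a stable envelope;
#'   smaller values give degenerate but still ordered bounds).
#' @param seed Integer seed.
#' @param standardize Standardize each simulated field before variography.
#' @param probs Lower/upper quantile probabilities.
#' @inheritParams empirical_variogram
#' @return A data frame of class `variogram_envelope` with columns
#'   `direction`, `lag`, `lower`, `upper`, `n_pairs`; attribute `n_sim`.
#' @export
variogram_envelope <- function(model, locations, n_sim = 1000, seed = NULL,
                               lag_width = 2, n_lags = 25, angular_tol = 15,
                               azimuth = 0, standardize = TRUE,
                               probs = c(0.025, 0.975)) {
  locations <- as.matrix(locations)
  pairs <- vgm_pairs(locations[, 1], locations[, 2], azimuth, lag_width,
                     n_lags, angular_tol)
  gam <- list(along = NULL, across = NULL)
  with_seed(seed, {
    chunk <- 200L
    done <- 0L
    while (done < n_sim) {
      m <- min(chunk, n_sim - done)
      z <- simulate_gaussian_field(locations, model, seed = NULL,
                                   n_sims = m, azimuth = azimuth)
      if (standardize) z <- scale(z)
      for (dir in c("along", "across")) {
        g <- gamma_from_pairs(pairs[[dir]], z, n_lags)$gamma
        gam[[dir]] <- cbind(gam[[dir]], g)
      }
      done <- done + m
    }
  })
  out <- do.call(rbind, lapply(c("along", "across"), function(dir) {
    qs <- t(apply(gam[[dir]], 1, stats::quantile, probs = probs,
                  na.rm = TRUE, names = FALSE))
    data.frame(direction = dir, lag = (seq_len(n_lags) - 0.5) * lag_width,
               lower = qs[, 1], upper = qs[, 2],
               n_pairs = tabulate(pairs[[dir]]$lag, n_lags))
  }))
  rownames(out) <- NULL
  class(out) <- c("variogram_envelope", "data.frame")
  attr(out, "n_sim") <- n_sim
  out
}

#' Test interannual stability of spatial structure against an envelope
#'
#' A year's spatial structure is called stable when its (standardized)
#' empirical variogram stays inside the simulation envelope of the mean
#' model at all but a small fraction of lags. Lags with no pairs in either
#' the annual variogram or the envelope are ignored.
#'
#' @param annual_variograms Either a single [empirical_variogram()] or a
#'   named list of them (one per year), computed on the same lag grid as
#'   the envelope.
#' @param envelope A [variogram_envelope()].
#' @param tolerance_fraction Maximum tolerated fraction of lags outside
#'   the envelope.
#' @return A data frame with one row per year: `year`, `n_lags`,
#'   `n_outside`, `fraction_outside`, `stable`.
#' @export
test_annual_stability <- function(annual_variograms, envelope,
                                  tolerance_fraction = 0.05) {
  if (inherits(annual_variograms, "empirical_variogram")) {
    annual_variograms <- list(annual_variograms)
  }
  if (is.null(names(annual_variograms))) {
    names(annual_variograms) <- seq_along(annual_variograms)
  }
  out <- do.call(rbind, lapply(names(annual_variograms), function(nm) {
    emp <- annual_variograms[[nm]]
    m <- merge(as.data.frame(emp), as.data.frame(envelope),
               by = c("direction", "lag"), suffixes = c("", ".env"))
    if (nrow(m) != nrow(emp)) stopf("lag grids of variogram and envelope differ")
    m <- m[m$n_pairs > 0 & m$n_pairs.env > 0 & is.finite(m$gamma), ]
    outside <- m$gamma < m$lower | m$gamma > m$upper
    data.frame(year = nm, n_lags = nrow(m), n_outside = sum(outside),
               fraction_outside = mean(outside),
               stable = mean(outside) <= tolerance_fraction)
  }))
  rownames(out) <- NULL
  out
}
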