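#' Nested anisotropic spherical variogram model
#'
#' A variogram model is a nugget plus one or two spherical components.
#' Anisotropy is geometric: each component has its own range along and
#' across transects but a single sill, so the two directional curves reach
#' the same sill at different distances.
#'
#' @param nugget Nugget variance (>= 0).
#' @param sill Vector of component sills (one per spherical structure).
#' @param range_along,range_across Component ranges (nm) in the
#'   along-transect and across-transect directions; recycled against
#'   `sill`.
#' @return An object of class `vgm_model`.
#' @export
#' @examples
#' m <- vgm_model(nugget = 0.1, sill = c(0.5, 0.4),
#'                range_along = c(4, 12), range_across = c(8, 24))
#' predict(m, h = 0:20, direction = "along")
vgm_model <- function(nugget = 0, sill = 1, range_along = 10,
                      range_across = range_along) {
  k <- length(sill)
  range_along <- rep_len(range_along, k)
  range_across <- rep_len(range_across, k)
  if (nugget < 0 || any(sill < 0) ||
      any(range_along <= 0) || any(range_across <= 0)) {
    stopf("nugget/sills must be >= 0 and ranges > 0")
  }
  structure(list(nugget = nugget,
                 structures = data.frame(type = rep("spherical", k),
                                         sill = sill,
                                         range_along = range_along,
                                         range_across = range_across)),
            class = "vgm_model")
}

# Unit spherical variogram: 1.5 u - 0.5 u^3 up to u = 1, then 1.
sph <- function(u) ifelse(u >= 1, 1, 1.5 * u - 0.5 * u^3)

#' @export
print.vgm_model <- function(x, ...) {
  cat(sprintf("Variogram model: nugget %.4g + %d spherical component(s)\n",
              x$nugget, nrow(x$structures)))
  s <- x$structures
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  sill %.4g, range along %.4g nm / across %.4g nm\n",
                s$sill[i], s$range_along[i], s$range_across[i]))
  }
  cat(sprintf("  total sill %.4g\n", total_sill(x)))
  invisible(x)
}

#' @export
coef.vgm_model <- function(object, ...) {
  s <- object$structures
  c(nugget = object$nugget,
    stats::setNames(s$sill, paste0("sill", seq_len(nrow(s)))),
    stats::setNames(s$range_along, paste0("range_along", seq_len(nrow(s)))),
    stats::setNames(s$range_across, paste0("range_across", seq_len(nrow(s)))))
}

#' Total sill of a variogram model
#' @param model A [vgm_model()].
#' @export
total_sill <- function(model) model$nugget + sum(model$structures$sill)

# Semivariance for separation vectors given in along/across components.
# Geometric anisotropy: each component is isotropic in coordinates scaled
# by its directional ranges. h = 0 exactly returns 0 (the nugget is a
# discontinuity at the origin).
vgm_gamma_vec <- function(model, d_along, d_across) {
  g <- numeric(length(d_along))
  s <- model$structures
  for (i in seq_len(nrow(s))) {
    u <- sqrt((d_along / s$range_along[i])^2 + (d_across / s$range_across[i])^2)
    g <- g + s$sill[i] * sph(u)
  }
  nonzero <- (d_along != 0) | (d_across != 0)
  g + model$nugget * nonzero
}

#' Evaluate a variogram model along a direction
#'
#' @param object A [vgm_model()].
#' @param h Lag distances (nm).
#' @param direction `"along"` or `"across"` (transect-relative).
#' @param ... Unused.
#' @return Semivariances at the requested lags.
#' @export
predict.vgm_model <- function(object, h, direction = c("along", "across"),
                              ...) {
  direction <- match.arg(direction)
  if (direction == "along") vgm_gamma_vec(object, h, 0 * h)
  else vgm_gamma_vec(object, 0 * h, h)
}

# Covariance corresponding to the model (finite-sill): C(h) = sill - gamma(h).
vgm_cov_vec <- function(model, d_along, d_across) {
  total_sill(model) - vgm_gamma_vec(model, d_along, d_across)
}

#' @export
plot.vgm_model <- function(x, max_lag = NULL, ...) {
  if (is.null(max_lag)) {
    max_lag <- 1.2 * max(x$structures$range_along, x$structures$range_across)
  }
  h <- seq(0, max_lag, length.out = 200)
  ga <- predict(x, h, "along"); gc <- predict(x, h, "across")
  graphics::plot(h, ga, type = "l", xlab = "lag (nm)",
                 ylab = expression(gamma(h)), ylim = c(0, 1.1 * total_sill(x)),
                 ...)
  graphics::lines(h, gc, lty = 2)
  graphics::legend("bottomright", legend = c("along", "across"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
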