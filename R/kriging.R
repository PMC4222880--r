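# Ordinary kriging with an anisotropic moving neighbourhood, average and
# variability maps, and recurrent / occasional / unfavourable area
# classification.

#' Anisotropic kriging neighbourhood
#'
#' Neighbours are searched inside an ellipse whose radii differ along and
#' across transects, so that with widely spaced transects every grid node
#' can still reach data on at least two transects. Defaults: 12 nm along,
#' 30 nm across, between 4 and 32 neighbours.
#'
#' @param radius_along,radius_across Search radii (nm).
#' @param min_neighbours Minimum data points required to krige a node.
#' @param max_neighbours Maximum data points used (nearest by scaled
#'   distance).
#' @return A list of class `neighbourhood_spec`.
#' @export
neighbourhood_spec <- function(radius_along = 12, radius_across = 30,
                               min_neighbours = 4, max_neighbours = 32) {
  if (radius_along <= 0 || radius_across <= 0) stopf("radii must be positive")
  if (min_neighbours < 1 || max_neighbours < min_neighbours) {
    stopf("need 1 <= min_neighbours <= max_neighbours")
  }
  structure(list(radius_along = radius_along, radius_across = radius_across,
                 min_neighbours = min_neighbours,
                 max_neighbours = max_neighbours),
            class = "neighbourhood_spec")
}

#' Interpolation grid over the sampled domain
#'
#' Regular grid of node centres at `resolution` spacing, masked to the
#' convex hull of the sample locations intersected with the design polygon
#' (when supplied).
#'
#' @param x,y Sample coordinates (nm).
#' @param resolution Grid step (nm).
#' @param polygon Optional two-column matrix of domain vertices (nm).
#' @return Data frame with `x`, `y` for masked-in nodes only.
#' @export
make_grid <- function(x, y, resolution = 1, polygon = NULL) {
  hull <- cbind(x, y)[grDevices::chull(x, y), , drop = FALSE]
  gx <- seq(min(x), max(x), by = resolution)
  gy <- seq(min(y), max(y), by = resolution)
  g <- expand.grid(x = gx, y = gy)
  keep <- points_in_polygon(g$x, g$y, hull) |
    on_hull_boundary(g$x, g$y, hull)
  if (!is.null(polygon)) {
    keep <- keep & (points_in_polygon(g$x, g$y, polygon) |
                      on_hull_boundary(g$x, g$y, polygon))
  }
  g[keep, , drop = FALSE]
}

# Points lying (almost) exactly on a polygon edge, which the even-odd rule
# may classify either way.
on_hull_boundary <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  on <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- poly[j, 1] - poly[i, 1]; ey <- poly[j, 2] - poly[i, 2]
    len2 <- ex^2 + ey^2
    if (len2 == 0) next
    t <- ((px - poly[i, 1]) * ex + (py - poly[i, 2]) * ey) / len2
    t <- pmin(1, pmax(0, t))
    d2 <- (px - (poly[i, 1] + t * ex))^2 + (py - (poly[i, 2] + t * ey))^2
    on <- on | d2 < tol
  }
  on
}

#' Ordinary kriging on a grid with an anisotropic moving neighbourhood
#'
#' For every grid node, data points within the anisotropic search ellipse
#' (scaled distance \eqn{\sqrt{(\Delta_a/r_a)^2 + (\Delta_c/r_c)^2} \le 1})
#' are ranked by scaled distance and the nearest `max_neighbours` used to
#' solve the ordinary kriging system under the given variogram model.
#' Weights sum to one. Nodes with fewer than `min_neighbours` neighbours,
#' or with a singular kriging system, are flagged and left `NA` rather
#' than failing the whole map.
#'
#' @param x,y Data coordinates (nm).
#' @param values Data values (typically log-biomass).
#' @param model A [vgm_model()].
#' @param grid Data frame with node coordinates `x`, `y` (see
#'   [make_grid()]).
#' @param nbhd A [neighbourhood_spec()].
#' @param azimuth Along-transect direction (degrees clockwise from north).
#' @return A data frame of class `kriged_map`: `x`, `y`, `prediction`,
#'   `kriging_variance`, `n_neighbours`.
#' @export
krige <- function(x, y, values, model, grid,
                  nbhd = neighbourhood_spec(), azimuth = 0) {
  n <- length(x)
  if (n < nbhd$min_neighbours) stopf("fewer data points than min_neighbours")
  aa <- along_across(x, y, azimuth)
  ga <- along_across(grid$x, grid$y, azimuth)
  sill <- total_sill(model)
  pred <- rep(NA_real_, nrow(grid))
  kvar <- rep(NA_real_, nrow(grid))
  nuse <- integer(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    da <- aa[, "along"] - ga[g, "along"]
    dc <- aa[, "across"] - ga[g, "across"]
    sd2 <- (da / nbhd$radius_along)^2 + (dc / nbhd$radius_across)^2
    nb <- which(sd2 <= 1)
    if (length(nb) < nbhd$min_neighbours) next
    if (length(nb) > nbhd$max_neighbours) {
      nb <- nb[order(sd2[nb])[seq_len(nbhd$max_neighbours)]]
    }
    m <- length(nb)
    # covariance form of the OK system
    Caa <- vgm_cov_vec(model,
                       outer(aa[nb, "along"], aa[nb, "along"], "-"),
                       outer(aa[nb, "across"], aa[nb, "across"], "-"))
    dim(Caa) <- c(m, m)
    c0 <- vgm_cov_vec(model, da[nb], dc[nb])
    A <- rbind(cbind(Caa, 1), c(rep(1, m), 0))
    rhs <- c(c0, 1)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    w <- sol[seq_len(m)]
    pred[g] <- sum(w * values[nb])
    kvar[g] <- max(0, sill - sum(w * c0) - sol[m + 1])
    nuse[g] <- m
  }
  out <- data.frame(x = grid$x, y = grid$y, prediction = pred,
                    kriging_variance = kvar, n_neighbours = nuse)
  class(out) <- c("kriged_map", "data.frame")
  out
}

#' Kriging weights at a single target (mainly for checking)
#'
#' Solves one ordinary kriging system with all supplied data (no
#' neighbourhood restriction) and returns the weights, prediction and
#' kriging variance.
#'
#' @inheritParams krige
#' @param x0,y0 Target location.
#' @export
krige_point <- function(x, y, values, model, x0, y0, azimuth = 0) {
  g <- krige(x, y, values, model, data.frame(x = x0, y = y0),
             nbhd = neighbourhood_spec(radius_along = Inf,
                                       radius_across = Inf,
                                       min_neighbours = 1,
                                       max_neighbours = length(x)),
             azimuth = azimuth)
  g
}

#' Average and variability maps from annual kriged maps
#'
#' Node-by-node mean and sample standard deviation of a set of annual
#' kriged maps sharing one grid.
#'
#' @param maps List of [krige()] outputs on identical grids.
#' @return Data frame `x`, `y`, `mean`, `sd` (class `avg_var_maps`).
#' @export
average_variability_maps <- function(maps) {
  if (length(maps) < 2) stopf("need >= 2 annual maps")
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (nrow(m) != nrow(ref) || any(m$x != ref$x) || any(m$y != ref$y)) {
      stopf("annual maps are not on the same grid")
    }
  }
  p <- sapply(maps, function(m) m$prediction)
  out <- data.frame(x = ref$x, y = ref$y,
                    mean = rowMeans(p),
                    sd = apply(p, 1, stats::sd))
  class(out) <- c("avg_var_maps", "data.frame")
  out
}

#' Classify recurrent, occasional and unfavourable areas
#'
#' Combines the average and variability maps: taking the medians of the
#' two maps over valid nodes as thresholds, nodes with high variability
#' (sd >= median) are `occasional`; among low-variability nodes, those
#' with high mean (>= median) are `recurrent` and the rest `unfavourable`.
#' Ties at the median count as "high" for both maps.
#'
#' @param avmaps Output of [average_variability_maps()], or a data frame
#'   with `x`, `y`, `mean`, `sd`.
#' @return Data frame `x`, `y`, `mean`, `sd`, `category` (factor) of class
#'   `area_classification`; attributes `median_mean`, `median_sd`.
#' @export
classify_areas <- function(avmaps) {
  ok <- is.finite(avmaps$mean) & is.finite(avmaps$sd)
  if (!any(ok)) stopf("no valid nodes to classify")
  mm <- stats::median(avmaps$mean[ok])
  ms <- stats::median(avmaps$sd[ok])
  cat_ <- rep(NA_character_, nrow(avmaps))
  cat_[ok] <- ifelse(avmaps$sd[ok] >= ms, "occasional",
                     ifelse(avmaps$mean[ok] >= mm, "recurrent",
                            "unfavourable"))
  out <- data.frame(x = avmaps$x, y = avmaps$y, mean = avmaps$mean,
                    sd = avmaps$sd,
                    category = factor(cat_, levels = c("recurrent",
                                                       "occasional",
                                                       "unfavourable")))
  class(out) <- c("area_classification", "data.frame")
  attr(out, "median_mean") <- mm
  attr(out, "median_sd") <- ms
  out
}

#' @export
plot.kriged_map <- function(x, ...) {
  ok <- is.finite(x$prediction)
  pal <- grDevices::hcl.colors(12, "viridis")
  cut_ <- cut(x$prediction[ok], 12)
  graphics::plot(x$x[ok], x$y[ok], col = pal[as.integer(cut_)], pch = 15,
                 xlab = "x (nm)", ylab = "y (nm)", asp = 1, ...)
  invisible(x)
}
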