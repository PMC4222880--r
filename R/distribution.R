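# Spatial distribution indicators: centre of gravity and inertia,
# anisotropic recursive patch identification, EOF of annual maps, and the
# pointwise coefficient of variation of relative biomass.

#' Centre of gravity of a biomass distribution
#'
#' Biomass-weighted mean location of the population.
#'
#' @param x,y Planar coordinates (nm).
#' @param weights Biomass per point (>= 0, positive total).
#' @return Named vector `c(x, y)`.
#' @export
centre_of_gravity <- function(x, y, weights = rep(1, length(x))) {
  if (any(weights < 0)) stopf("negative weights")
  w <- sum(weights)
  if (w <= 0) stopf("total weight must be positive")
  c(x = sum(weights * x) / w, y = sum(weights * y) / w)
}

#' Inertia, principal axes and inertia ellipse
#'
#' Inertia is the biomass-weighted mean squared distance to the centre of
#' gravity (nm^2); its square root is the RMS distance of a fish to the
#' population centre. The principal axes come from the eigen-decomposition
#' of the weighted coordinate covariance; the inertia ellipse is drawn at
#' one sigma (semi-axes = square roots of the principal variances), a
#' convention used consistently by the overlap indices.
#'
#' @inheritParams centre_of_gravity
#' @return An object of class `gravity_stats`: list with `cg`, `inertia`,
#'   `axes` (2x2 matrix of principal directions in columns), `axis_var`
#'   (principal variances, summing to the inertia), and `ellipse`
#'   (centre, semi-axes `a >= b`, orientation in radians).
#' @export
inertia <- function(x, y, weights = rep(1, length(x))) {
  cg <- centre_of_gravity(x, y, weights)
  w <- weights / sum(weights)
  dx <- x - cg["x"]; dy <- y - cg["y"]
  cov <- matrix(c(sum(w * dx * dx), sum(w * dx * dy),
                  sum(w * dx * dy), sum(w * dy * dy)), 2, 2)
  eig <- eigen(cov, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  structure(list(cg = cg, inertia = sum(vals), axes = eig$vectors,
                 axis_var = vals,
                 ellipse = list(centre = cg, a = sqrt(vals[1]),
                                b = sqrt(vals[2]),
                                angle = atan2(eig$vectors[2, 1],
                                              eig$vectors[1, 1]))),
            class = "gravity_stats")
}

#' @export
print.gravity_stats <- function(x, ...) {
  cat(sprintf("CG (%.2f, %.2f) nm; inertia %.1f nm^2 (RMS distance %.1f nm)\n",
              x$cg["x"], x$cg["y"], x$inertia, sqrt(x$inertia)))
  cat(sprintf("  ellipse semi-axes %.2f x %.2f nm, orientation %.1f deg\n",
              x$ellipse$a, x$ellipse$b, x$ellipse$angle * 180 / pi))
  invisible(x)
}

#' Identify biomass patches by anisotropic recursive assignment
#'
#' Presence samples are processed in decreasing biomass order. The richest
#' sample founds the first patch; each subsequent sample joins the patch
#' whose running biomass-weighted centre of gravity is nearest in the
#' anisotropy-scaled distance
#' \eqn{d = \sqrt{(\Delta_{along}/d_{along})^2 + (\Delta_{across}/d_{across})^2}}
#' provided \eqn{d \le 1}, and founds a new patch otherwise. Distance ties
#' go to the earlier-created patch; equal-biomass samples are processed in
#' input order. The anisotropic thresholds compensate for transect spacing
#' being far wider than the along-transect sampling step (defaults 6 nm
#' along, 24 nm across). Patches holding less than `min_share` of total
#' biomass are flagged as not retained rather than deleted, so biomass
#' accounting stays closed.
#'
#' @param x,y Planar coordinates (nm).
#' @param values Biomass per point (some must be positive).
#' @param d_along,d_across Joining thresholds (nm) along and across
#'   transects.
#' @param min_share Minimum biomass share for a patch to be retained.
#' @param azimuth Along-transect direction (degrees clockwise from north).
#' @return A list of class `patch_set`: `patches` is a data frame (one row
#'   per patch: `patch_id`, `cg_x`, `cg_y`, `inertia`, `n`, `biomass`,
#'   `biomass_share`, `retained`), `assignment` maps each presence sample
#'   (index into the input) to its patch.
#' @export
identify_patches <- function(x, y, values, d_along = 6, d_across = 24,
                             min_share = 0.10, azimuth = 0) {
  if (d_along <= 0 || d_across <= 0) stopf("thresholds must be positive")
  if (any(values < 0)) stopf("negative biomass")
  pres <- which(values > 0)
  if (length(pres) == 0) stopf("no presence points")
  aa <- along_across(x, y, azimuth)
  ord <- pres[order(-values[pres])]   # stable: ties keep input order
  patch_of <- integer(length(ord))
  cg_a <- numeric(0); cg_c <- numeric(0); wsum <- numeric(0)
  for (k in seq_along(ord)) {
    i <- ord[k]
    if (length(wsum) == 0) {
      d <- numeric(0)
    } else {
      d <- sqrt(((aa[i, "along"] - cg_a) / d_along)^2 +
                  ((aa[i, "across"] - cg_c) / d_across)^2)
    }
    if (length(d) && min(d) <= 1) {
      p <- which.min(d)               # which.min takes the earliest tie
    } else {
      p <- length(wsum) + 1L
      cg_a[p] <- 0; cg_c[p] <- 0; wsum[p] <- 0
    }
    w <- values[i]
    cg_a[p] <- (cg_a[p] * wsum[p] + aa[i, "along"] * w) / (wsum[p] + w)
    cg_c[p] <- (cg_c[p] * wsum[p] + aa[i, "across"] * w) / (wsum[p] + w)
    wsum[p] <- wsum[p] + w
    patch_of[k] <- p
  }
  total <- sum(values[pres])
  patches <- do.call(rbind, lapply(seq_along(wsum), function(p) {
    idx <- ord[patch_of == p]
    g <- inertia(x[idx], y[idx], values[idx])
    data.frame(patch_id = p, cg_x = unname(g$cg["x"]),
               cg_y = unname(g$cg["y"]), inertia = g$inertia,
               n = length(idx), biomass = sum(values[idx]),
               biomass_share = sum(values[idx]) / total)
  }))
  patches$retained <- patches$biomass_share >= min_share
  assignment <- data.frame(index = ord, patch_id = patch_of)
  structure(list(patches = patches, assignment = assignment,
                 d_along = d_along, d_across = d_across),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("%d patch(es), %d retained (share >= threshold)\n",
              nrow(x$patches), sum(x$patches$retained)))
  print(x$patches, digits = 3)
  invisible(x)
}

#' Empirical orthogonal function decomposition of annual maps
#'
#' Decomposes a year x location matrix into orthogonal spatial patterns
#' (EOFs) and their annual amplitudes, via the singular value
#' decomposition. Rows (years) are first standardized so that years are
#' compared independently of their total biomass level: mode `"relative"`
#' divides each year by its total, mode `"zscore"` z-scores each year,
#' mode `"none"` leaves rows untouched. Each row is then centred (its
#' mean removed) before decomposition, so a year identical to another
#' contributes an identical centred profile.
#'
#' @param annual_maps Numeric matrix, years in rows, locations in columns,
#'   no missing cells.
#' @param standardization `"relative"`, `"zscore"` or `"none"`.
#' @return An object of class `eof_result`: `eigenvalues` (variance per
#'   axis, non-increasing), `pct_variance` (summing to 100), `year_scores`
#'   (years x axes amplitudes), `point_loadings` (locations x axes
#'   patterns), `year_correlations` (correlation of each year's profile
#'   with each loading), and `centred` (the decomposed matrix).
#' @export
eof <- function(annual_maps, standardization = c("relative", "zscore",
                                                 "none")) {
  standardization <- match.arg(standardization)
  m <- as.matrix(annual_maps)
  if (nrow(m) < 2 || ncol(m) < 2) stopf("need >= 2 years and >= 2 locations")
  if (anyNA(m)) stopf("missing cells; restrict to common locations first")
  if (standardization == "relative") {
    tot <- rowSums(m)
    if (any(tot <= 0)) stopf("a year has non-positive total biomass")
    m <- m / tot
  } else if (standardization == "zscore") {
    m <- t(scale(t(m)))
  }
  centred <- m - rowMeans(m)
  sv <- svd(centred)
  ev <- sv$d^2
  keep <- seq_len(min(dim(centred)))
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  ycor <- suppressWarnings(stats::cor(t(centred), sv$v))
  structure(list(eigenvalues = ev[keep],
                 pct_variance = 100 * ev[keep] / sum(ev),
                 year_scores = scores[, keep, drop = FALSE],
                 point_loadings = sv$v[, keep, drop = FALSE],
                 year_correlations = ycor[, keep, drop = FALSE],
                 centred = centred),
            class = "eof_result")
}

#' @export
print.eof_result <- function(x, n_axes = 4, ...) {
  k <- min(n_axes, length(x$pct_variance))
  cat("EOF decomposition of annual maps\n")
  cat("  % variance per axis:",
      paste(sprintf("%.1f", x$pct_variance[seq_len(k)]), collapse = ", "),
      "...\n")
  invisible(x)
}

#' Pointwise coefficient of variation of relative biomass
#'
#' At every sampling location, the CV across years (sample SD / mean) of
#' relative biomass (each year's biomass divided by that year's total), so
#' that the CV reflects changes in geographical location rather than in
#' overall biomass. Values above 1 indicate overdispersion. Locations with
#' zero mean are returned as `NA`.
#'
#' @param relative_biomass Year x location matrix of relative biomass;
#'   every row must sum to 1 (checked to 1e-6).
#' @return Numeric vector of CVs per location (NA where the species never
#'   occurred).
#' @export
pointwise_cv <- function(relative_biomass) {
  m <- as.matrix(relative_biomass)
  if (nrow(m) < 2) stopf("need >= 2 years")
  if (any(abs(rowSums(m) - 1) > 1e-6)) {
    stopf("rows of relative biomass must each sum to 1")
  }
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  ifelse(mu > 0, s / mu, NA_real_)
}
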