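# Interspecific collocation indices at three scales: inertia-ellipse
# overlap (global), patch-ellipse overlap (intermediate), co-occurrence,
# local index of collocation and dominance (local), with randomization
# tests.

# Polygonal approximation of an ellipse (centre, semi-axes a/b, angle in
# radians), counter-clockwise.
ellipse_polygon <- function(ellipse, n_vertices = 720) {
  t <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  ca <- cos(ellipse$angle); sa <- sin(ellipse$angle)
  ex <- ellipse$a * cos(t); ey <- ellipse$b * sin(t)
  cbind(x = ellipse$centre[[1]] + ex * ca - ey * sa,
        y = ellipse$centre[[2]] + ex * sa + ey * ca)
}

# Shoelace area of a simple polygon.
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Sutherland-Hodgman clipping of polygon `subject` by convex polygon
# `clip` (both counter-clockwise). Returns the intersection polygon (or a
# 0-row matrix).
clip_convex <- function(subject, clip) {
  out <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    if (nrow(out) == 0) return(out)
    a <- clip[i, ]; b <- clip[if (i == n) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    m <- nrow(inp)
    sides <- ex * (inp[, 2] - a[2]) - ey * (inp[, 1] - a[1])
    for (k in seq_len(m)) {
      cur <- inp[k, ]; prev <- inp[if (k == 1) m else k - 1L, ]
      scur <- sides[k]; sprev <- sides[if (k == 1) m else k - 1L]
      if (scur >= 0) {
        if (sprev < 0) {
          t <- sprev / (sprev - scur)
          out <- rbind(out, prev + t * (cur - prev))
        }
        out <- rbind(out, cur)
      } else if (sprev >= 0) {
        t <- sprev / (sprev - scur)
        out <- rbind(out, prev + t * (cur - prev))
      }
    }
  }
  out
}

# Ensure counter-clockwise orientation.
ccw <- function(p) {
  s <- sum(p[, 1] * c(p[-1, 2], p[1, 2]) - c(p[-1, 1], p[1, 1]) * p[, 2]) / 2
  if (s < 0) p[rev(seq_len(nrow(p))), ] else p
}

#' Overlap index of two inertia ellipses
#'
#' Intersection-over-union of the two ellipse areas: 0 when the ellipses
#' are disjoint, 1 when they coincide. Areas are computed on 720-vertex
#' polygonal approximations; the intersection is obtained by convex
#' polygon clipping. Degenerate (zero-area) ellipses give 0 unless both
#' collapse to the same point, which gives 1.
#'
#' @param e1,e2 Ellipses as produced by [inertia()] (`$ellipse`: list with
#'   `centre`, `a`, `b`, `angle`), or `gravity_stats` objects.
#' @param n_vertices Vertices of the polygonal approximation.
#' @return Overlap index in [0, 1]; symmetric in its arguments.
#' @export
ellipse_overlap <- function(e1, e2, n_vertices = 720) {
  if (inherits(e1, "gravity_stats")) e1 <- e1$ellipse
  if (inherits(e2, "gravity_stats")) e2 <- e2$ellipse
  deg1 <- e1$a <= 0 || e1$b <= 0
  deg2 <- e2$a <= 0 || e2$b <= 0
  if (deg1 || deg2) {
    same_pt <- deg1 && deg2 &&
      isTRUE(all.equal(unlist(e1$centre), unlist(e2$centre),
                       check.attributes = FALSE))
    return(if (same_pt) 1 else 0)
  }
  p1 <- ccw(ellipse_polygon(e1, n_vertices))
  p2 <- ccw(ellipse_polygon(e2, n_vertices))
  a1 <- polygon_area(p1); a2 <- polygon_area(p2)
  inter <- clip_convex(p1, p2)
  ai <- if (nrow(inter) >= 3) polygon_area(inter) else 0
  ai / (a1 + a2 - ai)
}

#' Overlap of patch-ellipse unions of two species
#'
#' Intersection-over-union of the unions of the retained patches' inertia
#' ellipses for the two species, evaluated by counting nodes of a fine
#' regular grid over the joint bounding box (point-in-ellipse membership
#' is analytic, so the only approximation is the grid resolution).
#'
#' @param patches_i,patches_j Data frames describing each species' patch
#'   ellipses: columns `cg_x`, `cg_y`, `a`, `b`, `angle` (see
#'   [patch_ellipses()]), or `patch_set` objects together with the point
#'   data via [patch_ellipses()].
#' @param grid_n Grid nodes per axis.
#' @return Overlap index in [0, 1].
#' @export
patch_overlap <- function(patches_i, patches_j, grid_n = 400) {
  ei <- patches_i; ej <- patches_j
  if (nrow(ei) == 0 || nrow(ej) == 0) {
    stopf("each species needs at least one retained patch ellipse")
  }
  all_e <- rbind(ei, ej)
  r <- pmax(all_e$a, all_e$b)
  xr <- range(all_e$cg_x - r, all_e$cg_x + r)
  yr <- range(all_e$cg_y - r, all_e$cg_y + r)
  gx <- seq(xr[1], xr[2], length.out = grid_n)
  gy <- seq(yr[1], yr[2], length.out = grid_n)
  g <- expand.grid(x = gx, y = gy)
  in_union <- function(e) {
    inside <- rep(FALSE, nrow(g))
    for (k in seq_len(nrow(e))) {
      if (e$a[k] <= 0 || e$b[k] <= 0) next
      ca <- cos(e$angle[k]); sa <- sin(e$angle[k])
      dx <- g$x - e$cg_x[k]; dy <- g$y - e$cg_y[k]
      u <- (dx * ca + dy * sa) / e$a[k]
      v <- (-dx * sa + dy * ca) / e$b[k]
      inside <- inside | (u^2 + v^2 <= 1)
    }
    inside
  }
  ui <- in_union(ei); uj <- in_union(ej)
  denom <- sum(ui | uj)
  if (denom == 0) return(0)
  sum(ui & uj) / denom
}

#' Inertia ellipses of the retained patches of a patch set
#'
#' @param patch_set Output of [identify_patches()].
#' @param x,y,values The point data the patches were identified on.
#' @param retained_only Keep only retained patches.
#' @return Data frame `patch_id`, `cg_x`, `cg_y`, `a`, `b`, `angle`.
#' @export
patch_ellipses <- function(patch_set, x, y, values, retained_only = TRUE) {
  ids <- patch_set$patches$patch_id
  if (retained_only) ids <- ids[patch_set$patches$retained]
  out <- do.call(rbind, lapply(ids, function(p) {
    idx <- patch_set$assignment$index[patch_set$assignment$patch_id == p]
    g <- inertia(x[idx], y[idx], values[idx])
    data.frame(patch_id = p, cg_x = unname(g$cg["x"]),
               cg_y = unname(g$cg["y"]), a = g$ellipse$a, b = g$ellipse$b,
               angle = g$ellipse$angle)
  }))
  if (is.null(out)) out <- data.frame(patch_id = integer(0), cg_x = numeric(0),
                                      cg_y = numeric(0), a = numeric(0),
                                      b = numeric(0), angle = numeric(0))
  out
}

#' Local co-occurrence index of two species
#'
#' Proportion of sampling points where both species are present, among
#' points where at least one is present.
#'
#' @param zi,zj Per-EDSU biomass of the two species (same locations).
#' @return Index in [0, 1].
#' @export
cooccurrence_index <- function(zi, zj) {
  either <- zi > 0 | zj > 0
  if (!any(either)) stopf("both species absent everywhere")
  sum(zi > 0 & zj > 0) / sum(either)
}

#' Local index of collocation (LIC)
#'
#' Cosine similarity of the two species' density vectors over the shared
#' sampling points:
#' \eqn{\sum z_i z_j / \sqrt{\sum z_i^2 \sum z_j^2}}. 1 when densities are
#' proportional, 0 when supports are disjoint; invariant to rescaling
#' either species.
#'
#' @inheritParams cooccurrence_index
#' @return Index in [0, 1].
#' @export
local_index_of_collocation <- function(zi, zj) {
  si <- sum(zi^2); sj <- sum(zj^2)
  if (si <= 0 || sj <= 0) stopf("a species is absent everywhere")
  sum(zi * zj) / sqrt(si * sj)
}

#' Dominance index of two species per sampling point
#'
#' \eqn{(z_i - z_j)/(z_i + z_j)} wherever at least one species is present:
#' 1 where only species i occurs, -1 where only species j occurs, 0 where
#' both are equally abundant; `NA` (flagged, not an error) where both are
#' absent. Antisymmetric under swapping the species.
#'
#' @inheritParams cooccurrence_index
#' @return Numeric vector in [-1, 1] with `NA` at double absences.
#' @export
dominance_index <- function(zi, zj) {
  s <- zi + zj
  ifelse(s > 0, (zi - zj) / s, NA_real_)
}

#' Randomization test of a local collocation index
#'
#' Builds the null distribution of the index by resampling the second
#' species' values across sampling locations (bootstrap with replacement
#' by default, or permutation), keeping the first species' spatial pattern
#' fixed. The two-sided p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{|T^* - \bar T^*| \ge |T - \bar T^*|\})/(B + 1)}, so
#' the smallest attainable p is \eqn{1/(B+1)}.
#'
#' @inheritParams cooccurrence_index
#' @param index `"lic"` or `"cooccurrence"`.
#' @param n_resamples Number of resamples (>= 99).
#' @param seed Integer seed.
#' @param method `"bootstrap"` (with replacement) or `"permutation"`.
#' @return List with `observed`, `p_value`, `null_mean`, `n_resamples`.
#' @export
randomization_test <- function(zi, zj, index = c("lic", "cooccurrence"),
                               n_resamples = 1000, seed = NULL,
                               method = c("bootstrap", "permutation")) {
  index <- match.arg(index)
  method <- match.arg(method)
  if (n_resamples < 99) stopf("n_resamples must be >= 99")
  f <- switch(index, lic = local_index_of_collocation,
              cooccurrence = cooccurrence_index)
  obs <- f(zi, zj)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      zs <- if (method == "bootstrap") sample(zj, replace = TRUE)
            else sample(zj)
      tryCatch(f(zi, zs), error = function(e) NA_real_)
    }, numeric(1))
  })
  nulls <- nulls[is.finite(nulls)]
  if (length(nulls) == 0) stopf("index undefined in every resample")
  if (stats::sd(nulls) == 0 && isTRUE(all.equal(obs, nulls[1]))) {
    warning("index is constant under resampling; p = 1")
    return(list(observed = obs, p_value = 1, null_mean = mean(nulls),
                n_resamples = length(nulls)))
  }
  centre <- mean(nulls)
  p <- (1 + sum(abs(nulls - centre) >= abs(obs - centre))) /
    (length(nulls) + 1)
  list(observed = obs, p_value = p, null_mean = centre,
       n_resamples = length(nulls))
}

#' Pairwise collocation table across years
#'
#' Computes, for one species pair and every year of a survey dataset, the
#' global overlap (inertia ellipses), intermediate overlap (retained
#' patch ellipses), co-occurrence, LIC, and randomization p-values for the
#' two local indices.
#'
#' @param dataset A `survey_dataset`.
#' @param species_i,species_j Species names.
#' @param d_along,d_across,min_share Patch parameters, see
#'   [identify_patches()].
#' @param n_resamples,seed Randomization-test parameters.
#' @return Data frame with one row per year (class `collocation_table`).
#' @export
collocation_table <- function(dataset, species_i, species_j, d_along = 6,
                              d_across = 24, min_share = 0.10,
                              n_resamples = 1000, seed = NULL) {
  azimuth <- dataset$design$transect_azimuth
  rows <- lapply(seq_along(dataset$years), function(k) {
    yr <- dataset$years[k]
    rec <- dataset$records[dataset$records$year == yr, ]
    zi <- rec[[species_i]]; zj <- rec[[species_j]]
    res <- data.frame(species_i = species_i, species_j = species_j,
                      year = yr, global_overlap = NA_real_,
                      patch_overlap = NA_real_, cooccurrence = NA_real_,
                      lic = NA_real_, p_cooccurrence = NA_real_,
                      p_lic = NA_real_)
    if (sum(zi) <= 0 || sum(zj) <= 0) return(res)
    gi <- inertia(rec$x, rec$y, zi); gj <- inertia(rec$x, rec$y, zj)
    res$global_overlap <- ellipse_overlap(gi, gj)
    pi_ <- identify_patches(rec$x, rec$y, zi, d_along, d_across, min_share,
                            azimuth)
    pj_ <- identify_patches(rec$x, rec$y, zj, d_along, d_across, min_share,
                            azimuth)
    ei <- patch_ellipses(pi_, rec$x, rec$y, zi)
    ej <- patch_ellipses(pj_, rec$x, rec$y, zj)
    ei <- ei[ei$a > 0 & ei$b > 0, ]; ej <- ej[ej$a > 0 & ej$b > 0, ]
    if (nrow(ei) && nrow(ej)) res$patch_overlap <- patch_overlap(ei, ej)
    res$cooccurrence <- cooccurrence_index(zi, zj)
    res$lic <- local_index_of_collocation(zi, zj)
    sd_base <- if (is.null(seed)) NULL else seed + k
    res$p_cooccurrence <- randomization_test(zi, zj, "cooccurrence",
                                             n_resamples, sd_base)$p_value
    res$p_lic <- randomization_test(zi, zj, "lic", n_resamples,
                                    if (is.null(sd_base)) NULL
                                    else sd_base + 10000L)$p_value
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("collocation_table", "data.frame")
  out
}
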