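# Independent oracle implementations used to cross-check the package.
# These are deliberately written as plain double loops / direct formulas,
# sharing no code with the implementation they check.

# Brute-force bidirectional variogram: explicit double loop over ordered
# pairs, trigonometric direction classing.
oracle_variogram <- function(x, y, values, direction, lag_width, n_lags,
                             angular_tol = 15, azimuth = 0) {
  gamma_sum <- numeric(n_lags)
  count <- integer(n_lags)
  a <- azimuth * pi / 180
  ux <- sin(a); uy <- cos(a)           # along-transect unit vector
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      d <- sqrt(dx^2 + dy^2)
      if (d == 0) next
      k <- floor(d / lag_width) + 1
      if (k > n_lags) next
      cosang <- abs(dx * ux + dy * uy) / d
      cosang <- min(1, max(-1, cosang))
      ang_to_along <- acos(cosang) * 180 / pi
      hit <- if (direction == "along") ang_to_along <= angular_tol
             else (90 - ang_to_along) <= angular_tol
      if (hit) {
        gamma_sum[k] <- gamma_sum[k] + (values[i] - values[j])^2
        count[k] <- count[k] + 1
      }
    }
  }
  list(gamma = ifelse(count > 0, gamma_sum / (2 * count), NA),
       n_pairs = count)
}

# Gini coefficient by the mean-absolute-pairwise-difference formula.
oracle_gini <- function(v) {
  n <- length(v)
  s <- 0
  for (i in seq_len(n)) s <- s + sum(abs(v[i] - v))
  s / (2 * n^2 * mean(v))
}

# Step-by-step re-implementation of the greedy anisotropic patch
# recursion, tracking running centres of gravity explicitly.
oracle_patches <- function(x, y, values, d_along, d_across, azimuth = 0) {
  a <- azimuth * pi / 180
  al <- x * sin(a) + y * cos(a)
  ac <- x * cos(a) - y * sin(a)
  pres <- which(values > 0)
  pres <- pres[order(values[pres], decreasing = TRUE)]
  patches <- list()   # each: list(members, cga, cgc, w)
  assign <- integer(0)
  for (i in pres) {
    best <- 0; bestd <- Inf
    for (p in seq_along(patches)) {
      dd <- sqrt(((al[i] - patches[[p]]$cga) / d_along)^2 +
                   ((ac[i] - patches[[p]]$cgc) / d_across)^2)
      if (dd < bestd) { bestd <- dd; best <- p }
    }
    if (best > 0 && bestd <= 1) {
      pt <- patches[[best]]
      w <- pt$w + values[i]
      patches[[best]] <- list(members = c(pt$members, i),
                              cga = (pt$cga * pt$w + al[i] * values[i]) / w,
                              cgc = (pt$cgc * pt$w + ac[i] * values[i]) / w,
                              w = w)
      assign <- c(assign, best)
    } else {
      patches[[length(patches) + 1]] <-
        list(members = i, cga = al[i], cgc = ac[i], w = values[i])
      assign <- c(assign, length(patches))
    }
  }
  list(order = pres, patch_id = assign,
       members = lapply(patches, `[[`, "members"))
}

# Textbook ordinary kriging with all data, solved in semivariance form
# (the implementation uses the covariance form).
oracle_ok <- function(x, y, values, model, x0, y0, azimuth = 0) {
  a <- azimuth * pi / 180
  al <- x * sin(a) + y * cos(a); ac <- x * cos(a) - y * sin(a)
  al0 <- x0 * sin(a) + y0 * cos(a); ac0 <- x0 * cos(a) - y0 * sin(a)
  n <- length(x)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      G[i, j] <- pelagostat:::vgm_gamma_vec(model, al[i] - al[j],
                                            ac[i] - ac[j])
    }
  }
  g0 <- vapply(seq_len(n), function(i) {
    pelagostat:::vgm_gamma_vec(model, al[i] - al0, ac[i] - ac0)
  }, numeric(1))
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  sol <- solve(A, c(g0, 1))
  w <- sol[seq_len(n)]
  list(prediction = sum(w * values), weights = w,
       variance = sum(w * g0) + sol[n + 1])
}

# Small deterministic multi-year dataset built from a fixed table.
make_toy_dataset <- function() {
  design <- survey_design(n_transects = 3, transect_spacing = 12,
                          transect_length = 10)
  spec <- simulation_spec(design = design,
                          scenarios = default_scenarios(3), n_years = 3,
                          seed = 7)
  simulate_survey(spec)
}
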