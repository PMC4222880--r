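# Internal helpers shared across modules.

# Evaluate `code` with the global RNG seeded to `seed`, restoring the previous
# RNG state afterwards so library functions never clobber a user's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Even-odd (ray casting) point-in-polygon test; vertices as a two-column
# matrix, polygon implicitly closed. Points on an edge may fall either side
# at machine precision; callers place grid nodes off polygon edges.
points_in_polygon <- function(px, py, poly) {
  nx <- poly[, 1]; ny <- poly[, 2]
  n <- length(nx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (ny[i] > py) != (ny[j] > py)
    if (any(cross)) {
      xint <- nx[i] + (py[cross] - ny[i]) / (ny[j] - ny[i]) * (nx[j] - nx[i])
      inside[cross] <- xor(inside[cross], px[cross] < xint)
    }
    j <- i
  }
  inside
}

# Rotate planar coordinates by `azimuth` degrees (clockwise from north) so
# that the first returned column is the along-transect coordinate and the
# second the across-transect coordinate.
along_across <- function(x, y, azimuth) {
  a <- azimuth * pi / 180
  # along-transect unit vector (sin a, cos a); across = its perpendicular
  cbind(along = x * sin(a) + y * cos(a),
        across = x * cos(a) - y * sin(a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
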