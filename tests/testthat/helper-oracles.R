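# Independent oracles used to cross-check the implementation.

## Ray-casting point-in-polygon test (crossing number), independent of
## the half-plane machinery.  Points very near an edge are ambiguous for
## this oracle; tests exclude them explicitly.
ray_cast_inside <- function(verts, px, py) {
  n <- nrow(verts)
  inside <- logical(length(px))
  for (q in seq_along(px)) {
    cross <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- verts[i, 1L]; yi <- verts[i, 2L]
      xj <- verts[j, 1L]; yj <- verts[j, 2L]
      if ((yi > py[q]) != (yj > py[q])) {
        xint <- xi + (py[q] - yi) / (yj - yi) * (xj - xi)
        if (px[q] < xint) cross <- !cross
      }
      j <- i
    }
    inside[q] <- cross
  }
  inside
}

## Brute-force membership: conjunction of every directional band
## constraint evaluated from scratch (sort-free, no shared code path).
brute_band_inside <- function(bands, px, py) {
  ok <- rep(TRUE, length(px))
  for (b in bands) {
    d <- py * cos(b$theta) - px * sin(b$theta)
    ok <- ok & d >= b$B_l & d <= b$B_u
  }
  ok
}

## Distance of each query point to the nearest band boundary (to screen
## out on-edge points before exact-agreement checks).
min_boundary_gap <- function(bands, px, py) {
  gap <- rep(Inf, length(px))
  for (b in bands) {
    d <- py * cos(b$theta) - px * sin(b$theta)
    gap <- pmin(gap, abs(d - b$B_l), abs(d - b$B_u))
  }
  gap
}

## Hand-rolled interpolated quantile at target rank p*(n-1)+1.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(x))] - s[lo])
}

## A reproducible standard bivariate-normal test cloud.
bvn_cloud <- function(n, r = 0, seed = 123) {
  set.seed(seed)
  z <- matrix(rnorm(2 * n), n, 2)
  cbind(z[, 1], r * z[, 1] + sqrt(1 - r^2) * z[, 2])
}
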