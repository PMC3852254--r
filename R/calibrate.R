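#' Realized significance level of a region
#'
#' The proportion of the points that fall outside the region — the
#' adequacy metric used throughout the package.  For a band-built region
#' this is the in-sample exclusion rate of the confidence polygon.
#'
#' @param points A point set.
#' @param region A \code{"convex_region"}.
#' @return The proportion m/n of points outside the region.
#' @export
realized_alpha <- function(points, region) {
  points <- as_points(points)
  mean(!region_contains(region, points))
}

## Precompute, for one point set and grid: the n x K signed-distance
## matrix and its column-sorted copy.  All bisection steps reuse these.
distance_cache <- function(points, grid) {
  theta <- as.numeric(grid)
  D <- outer(points[, 2L], cos(theta)) - outer(points[, 1L], sin(theta))
  list(D = D, Dsort = apply(D, 2L, sort), n = nrow(points),
       theta = theta, K = length(theta))
}

## Quantile (type 7) of every column of a sorted matrix at probability p.
sorted_col_quantile <- function(Dsort, p) {
  n <- nrow(Dsort)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  Dsort[lo, ] + (h - lo) * (Dsort[hi, ] - Dsort[lo, ])
}

## Count of points strictly outside any of the K bands at level alpha_t.
count_outside <- function(cache, alpha_t) {
  B_l <- sorted_col_quantile(cache$Dsort, alpha_t / 2)
  B_u <- sorted_col_quantile(cache$Dsort, 1 - alpha_t / 2)
  out <- rep(FALSE, cache$n)
  for (k in seq_len(cache$K))
    out <- out | cache$D[, k] < B_l[k] | cache$D[, k] > B_u[k]
  sum(out)
}

build_region_at <- function(cache, alpha_t) {
  B_l <- sorted_col_quantile(cache$Dsort, alpha_t / 2)
  B_u <- sorted_col_quantile(cache$Dsort, 1 - alpha_t / 2)
  bands <- lapply(seq_len(cache$K), function(k) {
    d <- cache$D[, k]
    S <- which(d < B_l[k] | d > B_u[k])
    structure(list(theta = cache$theta[k], alpha_dir = alpha_t,
                   B_l = B_l[k], B_u = B_u[k],
                   m_theta = length(S), S_theta = S, n = cache$n),
              class = "directional_band")
  })
  region_from_bands(bands)
}

#' Calibrate the per-direction level of the confidence polygon
#'
#' The polygon intersects quantile bands in many directions
#' simultaneously, so at per-direction level \code{alpha_t = alpha_d} its
#' realized exclusion rate exceeds the desired level \code{alpha_d}
#' (multiplicity).  This solves, by bisection on the monotone map
#' \eqn{\alpha_t \mapsto} realized level, for the per-direction level
#' \eqn{\alpha_t^* \in (0, \alpha_d]} whose polygon excludes a fraction of
#' points matching \code{alpha_d}.  The realized level is a step function
#' of \eqn{\alpha_t} (an empirical proportion), so on the final plateau
#' the largest \eqn{\alpha_t} whose realized level does not exceed
#' \code{alpha_d + tol} is returned — the widest region consistent with
#' the nominal level.
#'
#' @param points A point set with at least \code{max(20, 4/alpha_d)}
#'   points (a warning is issued below that size, where an empirical
#'   exclusion proportion is too coarse for calibration to be meaningful).
#' @param alpha_d Desired overall significance level in (0, 1).
#' @param grid A [direction_grid()] (or a number of directions K).
#' @param tol Calibration tolerance on the realized level; default
#'   \code{max(1e-4, 0.25/n)}.
#' @param max_iter Maximum bisection steps (default 60).
#' @return Object of class \code{"dqcr_calibration"}: a list with
#'   \code{alpha_t_star}, \code{alpha_e} (realized level of the returned
#'   region), \code{alpha_d}, \code{delta} (the uncalibrated discrepancy:
#'   realized level at \eqn{\alpha_t = \alpha_d} minus \code{alpha_d}),
#'   \code{iterations}, and the calibrated \code{region}.
#' @examples
#' set.seed(7)
#' pts <- cbind(rnorm(1000), rnorm(1000))
#' cal <- calibrate_alpha(pts, 0.05, direction_grid(36))
#' cal$alpha_e
#' @export
calibrate_alpha <- function(points, alpha_d, grid = direction_grid(100L),
                            tol = NULL, max_iter = 60L) {
  points <- as_points(points, min_n = 3L)
  if (!is.numeric(alpha_d) || length(alpha_d) != 1L ||
      alpha_d <= 0 || alpha_d >= 1)
    stop("alpha_d must be a single probability strictly inside (0, 1)")
  if (!inherits(grid, "direction_grid")) grid <- direction_grid(grid)
  n <- nrow(points)
  if (n < max(20, 4 / alpha_d))
    warning(sprintf(
      "n = %d is below max(20, 4/alpha_d) = %g; the empirical exclusion ",
      n, max(20, 4 / alpha_d)),
      "proportion is too coarse for the calibration to be meaningful")
  if (is.null(tol)) tol <- max(1e-4, 0.25 / n)

  cache <- distance_cache(points, grid)
  f <- function(a) count_outside(cache, a) / n

  f_hi <- f(alpha_d)
  delta <- f_hi - alpha_d
  iterations <- 1L
  if (f_hi <= alpha_d + tol) {
    alpha_t <- alpha_d
    alpha_e <- f_hi
  } else {
    eps <- alpha_d / 1000
    f_lo <- f(eps)
    iterations <- 2L
    if (f_lo > alpha_d + tol)
      stop(sprintf(
        paste0("calibration cannot bracket the target: realized level at ",
               "alpha_t = %.3g is already %.4g > alpha_d + tol = %.4g ",
               "(n = %d, K = %d); the data may be dominated by ties"),
        eps, f_lo, alpha_d + tol, n, cache$K))
    lo <- eps; hi <- alpha_d
    ## invariant: f(lo) <= alpha_d + tol < f(hi)
    while (iterations < max_iter && (hi - lo) > 1e-12 * alpha_d) {
      mid <- (lo + hi) / 2
      fm <- f(mid)
      iterations <- iterations + 1L
      if (fm <= alpha_d + tol) lo <- mid else hi <- mid
    }
    alpha_t <- lo
    alpha_e <- f(lo)
  }
  region <- build_region_at(cache, alpha_t)
  region$alpha_d <- alpha_d
  region$alpha_t_star <- alpha_t
  region$alpha_e <- alpha_e
  structure(
    list(alpha_t_star = alpha_t, alpha_e = alpha_e, alpha_d = alpha_d,
         delta = delta, iterations = iterations, tol = tol,
         n = n, K = cache$K, region = region),
    class = "dqcr_calibration")
}

#' @export
print.dqcr_calibration <- function(x, ...) {
  cat("Calibrated distribution-free confidence region\n")
  cat(sprintf("  n = %d points, K = %d directions\n", x$n, x$K))
  cat(sprintf("  desired alpha_d          : %.6g\n", x$alpha_d))
  cat(sprintf("  solved alpha_t*          : %.6g\n", x$alpha_t_star))
  cat(sprintf("  realized alpha_e         : %.6g\n", x$alpha_e))
  cat(sprintf("  uncalibrated discrepancy : %+.6g\n", x$delta))
  cat(sprintf("  bisection iterations     : %d\n", x$iterations))
  invisible(x)
}

#' Distribution-free confidence region for two parameters
#'
#' The headline constructor: builds the direction grid, calibrates the
#' per-direction level so the polygon's realized exclusion rate matches
#' the nominal level \code{alpha_d}, and returns the calibrated convex
#' polygon.  Calibration details are attached to the returned region
#' (\code{alpha_t_star}, \code{alpha_e}, \code{alpha_d}).
#'
#' @inheritParams calibrate_alpha
#' @param K Number of directions in the grid (default 100).
#' @return A \code{"convex_region"} (see [region_from_bands()]) with the
#'   calibration fields attached.
#' @examples
#' set.seed(11)
#' pts <- cbind(rnorm(2000), rnorm(2000))
#' r <- confidence_region(pts, alpha_d = 0.05, K = 36)
#' r$alpha_e
#' @export
confidence_region <- function(points, alpha_d = 0.05, K = 100L, tol = NULL) {
  calibrate_alpha(points, alpha_d, direction_grid(K), tol)$region
}
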