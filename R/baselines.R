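#' Parametric (normal-theory) confidence ellipse
#'
#' The classical ellipsoidal region for bivariate data: the set
#' \eqn{\{p : (p - \bar{x})^\top S^{-1} (p - \bar{x}) \le q\}} where
#' \eqn{\bar{x}} and \eqn{S} are the sample mean and covariance and
#' \eqn{q} is the chi-square(2 df) quantile at \eqn{1 - \alpha} (the
#' large-sample scaling; at the sample sizes used here it is practically
#' identical to the small-sample F scaling).  The boundary is discretized
#' into \code{n_arc} vertices.
#'
#' @param points A point set with at least 3 points and nonsingular
#'   sample covariance.
#' @param alpha Significance level in (0, 1).
#' @param n_arc Number of boundary vertices (default 256).
#' @param center,cov Optional known mean vector and covariance matrix;
#'   when supplied they replace the sample estimates (useful for
#'   closed-form checks).
#' @return A \code{"convex_region"} with \code{method = "ellipse"} and
#'   attributes \code{center}, \code{cov}, \code{chisq_q}.
#' @examples
#' e <- ellipse_region(cbind(rnorm(500), rnorm(500)), 0.05)
#' region_area(e)
#' @export
ellipse_region <- function(points, alpha = 0.05, n_arc = 256L,
                           center = NULL, cov = NULL) {
  points <- as_points(points, min_n = 3L)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly inside (0, 1)")
  if (is.null(center)) center <- colMeans(points)
  if (is.null(cov)) cov <- stats::cov(points)
  L <- tryCatch(chol(cov), error = function(e)
    stop("sample covariance is singular (degenerate data)"))
  q <- stats::qchisq(1 - alpha, df = 2)
  phi <- seq(0, 2 * pi, length.out = n_arc + 1L)[seq_len(n_arc)]
  circ <- cbind(cos(phi), sin(phi))
  verts <- sweep(sqrt(q) * circ %*% L, 2L, center, `+`)
  verts <- canonical_vertices(verts)
  new_convex_region(
    vertices = verts, halfplanes = NULL, method = "ellipse",
    extra = list(center = center, cov = cov, chisq_q = q, alpha_d = alpha))
}

#' Center-outward convex hull peeling depth
#'
#' Assigns every point its peeling layer index: the outermost convex hull
#' gets index 1, is removed, and the procedure repeats on the remainder,
#' incrementing the index, until all points are indexed.  Points on a
#' layer's hull boundary belong to that layer.
#'
#' @param points A point set.
#' @return Integer vector of layer indices (1 = outermost), one per point.
#' @export
hull_peel_depth <- function(points) {
  points <- as_points(points)
  n <- nrow(points)
  depth <- integer(n)
  remaining <- seq_len(n)
  layer <- 0L
  while (length(remaining) > 0L) {
    layer <- layer + 1L
    if (length(remaining) <= 2L) {
      depth[remaining] <- layer
      break
    }
    sub <- points[remaining, , drop = FALSE]
    on_hull <- unique(grDevices::chull(sub))
    ## chull omits interior points of degenerate (collinear) sets; catch
    ## collinear extremes by membership on the hull segment
    if (length(on_hull) < 3L) {
      depth[remaining] <- layer
      break
    }
    depth[remaining[on_hull]] <- layer
    remaining <- remaining[-on_hull]
  }
  depth
}

#' Convex-hull-peeling confidence region
#'
#' Peels convex hull layers from the outside in, accumulating the removed
#' fraction of points, and stops before the layer whose removal would push
#' the cumulative removed fraction above \code{alpha}; the region is the
#' convex hull of the surviving points.  Because whole layers must be
#' removed or kept together, the realized exclusion rate is quantized to
#' layer-sized jumps and (under this stop rule) never exceeds
#' \code{alpha}.
#'
#' @param points A point set with at least 3 points.
#' @param alpha Significance level in (0, 1).
#' @return A \code{"convex_region"} with \code{method = "peel"} and fields
#'   \code{n_removed}, \code{layers_removed}.
#' @examples
#' p <- hull_peel_region(cbind(rnorm(200), rnorm(200)), 0.1)
#' p$n_removed / 200  # <= 0.1
#' @export
hull_peel_region <- function(points, alpha = 0.05) {
  points <- as_points(points, min_n = 3L)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly inside (0, 1)")
  n <- nrow(points)
  depth <- hull_peel_depth(points)
  removed <- 0L
  layers_removed <- 0L
  for (l in seq_len(max(depth))) {
    size <- sum(depth == l)
    survivors_after <- n - removed - size
    if ((removed + size) / n > alpha || survivors_after < 3L) break
    removed <- removed + size
    layers_removed <- l
  }
  keep <- depth > layers_removed
  sub <- points[keep, , drop = FALSE]
  hull_idx <- unique(grDevices::chull(sub))
  if (length(hull_idx) < 3L)
    warning("surviving points are collinear; region is degenerate")
  verts <- canonical_vertices(sub[hull_idx, , drop = FALSE])
  new_convex_region(
    vertices = verts, halfplanes = NULL, method = "peel",
    extra = list(alpha_d = alpha, n_removed = removed,
                 layers_removed = layers_removed))
}
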