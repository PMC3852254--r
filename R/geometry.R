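#' Validate a bivariate point set
#'
#' Coerces a two-column object (matrix, data frame, or list of x/y vectors)
#' into the internal point-set representation used throughout the package:
#' an n x 2 numeric matrix with columns \code{x} and \code{y}.
#'
#' @param x A two-column numeric matrix or data frame, or a list/data frame
#'   with components \code{x} and \code{y}.
#' @param min_n Minimum number of points required (default 1; region
#'   construction requires at least 3).
#' @return An n x 2 numeric matrix with columns \code{x}, \code{y}.
#' @examples
#' as_points(cbind(rnorm(10), rnorm(10)))
#' @export
as_points <- function(x, min_n = 1L) {
  if (is.data.frame(x)) {
    if (all(c("x", "y") %in% names(x))) {
      x <- cbind(x = x$x, y = x$y)
    } else {
      x <- as.matrix(x[, 1:2])
    }
  }
  if (is.list(x) && !is.matrix(x) && all(c("x", "y") %in% names(x))) {
    x <- cbind(x = x$x, y = x$y)
  }
  if (!is.matrix(x) || ncol(x) < 2L)
    stop("points must be a two-column matrix or data frame")
  x <- x[, 1:2, drop = FALSE]
  storage.mode(x) <- "double"
  colnames(x) <- c("x", "y")
  if (!all(is.finite(x)))
    stop("all point coordinates must be finite")
  if (nrow(x) < min_n)
    stop(sprintf("at least %d points are required (got %d)", min_n, nrow(x)))
  x
}

#' Equally spaced direction grid on [0, pi)
#'
#' Directions at angles \code{theta} and \code{theta + pi} index the same
#' reference line, so a grid of K equally spaced angles on \eqn{[0, \pi)}
#' covers every line direction; the angular spacing is \eqn{\delta = \pi/K}.
#'
#' @param K Number of directions (positive integer).
#' @return Object of class \code{"direction_grid"}: a numeric vector of
#'   strictly increasing angles in radians, with attributes \code{K} and
#'   \code{delta}.
#' @examples
#' direction_grid(4)
#' @export
direction_grid <- function(K = 100L) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be a positive integer")
  angles <- seq(0, pi, length.out = K + 1L)[seq_len(K)]
  structure(angles, K = K, delta = pi / K, class = "direction_grid")
}

#' Signed perpendicular distances to a reference line
#'
#' For a reference line through the origin at angle \code{theta} to the
#' horizontal axis, returns the signed perpendicular distance of every
#' point, \eqn{d_i = y_i \cos\theta - x_i \sin\theta}.  The sign is
#' positive above the line for \code{theta = 0}; distances at
#' \code{theta + pi} are the negatives of those at \code{theta}.
#'
#' @param points A point set (see [as_points()]).
#' @param theta Angle of the reference line, in radians, in \eqn{[0, \pi)}.
#' @return Numeric vector of length n of signed distances.
#' @examples
#' signed_distances(rbind(c(2, 3)), 0)        # 3: distance to the x-axis
#' signed_distances(rbind(c(1, 1)), pi / 4)   # 0: on the line y = x
#' @export
signed_distances <- function(points, theta) {
  points <- as_points(points)
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta))
    stop("theta must be a single finite angle in radians")
  if (theta < 0 || theta >= pi)
    stop("theta must lie in [0, pi)")
  unname(points[, 2L] * cos(theta) - points[, 1L] * sin(theta))
}

#' Empirical quantile by linear interpolation of order statistics
#'
#' Sorts the values ascending and interpolates linearly between the two
#' order statistics whose ranks bracket the target rank
#' \eqn{p (n - 1) + 1}.  This is the standard interpolation definition
#' (type 7 in [stats::quantile()]); all common definitions agree closely
#' for large samples.  \code{p = 0} returns the minimum and \code{p = 1}
#' the maximum.
#'
#' @param values Nonempty numeric vector without NA/NaN.
#' @param p Probability (or vector of probabilities) in \eqn{[0, 1]}.
#' @return Numeric vector of quantiles, one per element of \code{p}.
#' @examples
#' empirical_quantile(1:100, 0.5)  # 50.5
#' @export
empirical_quantile <- function(values, p) {
  if (length(values) == 0L) stop("values must be nonempty")
  if (anyNA(values) || any(!is.finite(values)))
    stop("values must be finite and free of NA/NaN")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p must lie in [0, 1]")
  unname(stats::quantile(values, probs = p, type = 7, names = FALSE))
}

#' Directional quantile band
#'
#' Projects the points onto the normal of the reference line at angle
#' \code{theta} (see [signed_distances()]) and takes the two-tailed
#' empirical quantile interval of the distances: the lower boundary
#' \code{B_l} at probability \code{alpha_dir / 2} and the upper boundary
#' \code{B_u} at \code{1 - alpha_dir / 2}.  Points strictly outside the
#' interval form the out-of-band set; points exactly on a boundary count
#' as inside (a conservative tie rule).
#'
#' @param points A point set.
#' @param theta Reference-line angle in \eqn{[0, \pi)}.
#' @param alpha_dir Per-direction significance level in (0, 1).
#' @return Object of class \code{"directional_band"}: a list with
#'   \code{theta}, \code{alpha_dir}, \code{B_l}, \code{B_u}, the index set
#'   \code{S_theta} of out-of-band points and its size \code{m_theta}, and
#'   \code{n}.
#' @examples
#' set.seed(1)
#' pts <- cbind(rnorm(500), rnorm(500))
#' b <- directional_band(pts, pi / 3, 0.05)
#' b$m_theta / 500  # close to 0.05
#' @export
directional_band <- function(points, theta, alpha_dir) {
  points <- as_points(points)
  if (!is.numeric(alpha_dir) || length(alpha_dir) != 1L ||
      alpha_dir <= 0 || alpha_dir >= 1)
    stop("alpha_dir must be a single probability strictly inside (0, 1)")
  d <- signed_distances(points, theta)
  if (max(d) == min(d))
    warning("all directional distances are equal; band has zero width")
  B_l <- empirical_quantile(d, alpha_dir / 2)
  B_u <- empirical_quantile(d, 1 - alpha_dir / 2)
  S_theta <- which(d < B_l | d > B_u)
  structure(
    list(theta = theta, alpha_dir = alpha_dir, B_l = B_l, B_u = B_u,
         m_theta = length(S_theta), S_theta = S_theta, n = length(d)),
    class = "directional_band")
}

## Clip a convex polygon (vertex matrix, CCW) against half-plane
## a*x + b*y <= c by Sutherland-Hodgman.  Returns possibly empty matrix.
clip_halfplane <- function(verts, a, b, c) {
  nv <- nrow(verts)
  if (nv == 0L) return(verts)
  val <- a * verts[, 1L] + b * verts[, 2L] - c
  out <- matrix(numeric(0), 0L, 2L)
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    vi <- val[i]; vj <- val[j]
    if (vi <= 0) out <- rbind(out, verts[i, ])
    if ((vi < 0 && vj > 0) || (vi > 0 && vj < 0)) {
      t <- vi / (vi - vj)
      out <- rbind(out, verts[i, ] + t * (verts[j, ] - verts[i, ]))
    }
  }
  out
}

## Order vertices counter-clockwise around their centroid, starting from
## the vertex at the smallest atan2 angle; drops near-duplicate vertices.
canonical_vertices <- function(verts, tol = NULL) {
  if (nrow(verts) == 0L) return(verts)
  scale <- max(1, max(abs(verts)))
  if (is.null(tol)) tol <- 1e-9 * scale
  ctr <- colMeans(verts)
  ang <- atan2(verts[, 2L] - ctr[2L], verts[, 1L] - ctr[1L])
  verts <- verts[order(ang), , drop = FALSE]
  keep <- rep(TRUE, nrow(verts))
  if (nrow(verts) > 1L) {
    for (i in seq_len(nrow(verts))) {
      j <- if (i == nrow(verts)) 1L else i + 1L
      if (keep[i] && sum(abs(verts[i, ] - verts[j, ])) < tol && j != i)
        keep[j] <- FALSE
    }
  }
  v <- verts[keep, , drop = FALSE]
  colnames(v) <- c("x", "y")
  v
}

new_convex_region <- function(vertices, halfplanes = NULL, alpha_dir = NA_real_,
                              n_directions = NA_integer_, method = "distfree",
                              extra = list()) {
  structure(
    c(list(vertices = vertices, halfplanes = halfplanes,
           alpha_dir = alpha_dir, n_directions = n_directions,
           method = method), extra),
    class = "convex_region")
}

#' Confidence polygon from directional bands
#'
#' Intersects the slabs \eqn{B_l(\theta_k) \le d(p, \theta_k) \le
#' B_u(\theta_k)} over all supplied directions into a convex polygon.  The
#' polygon is computed by incrementally clipping a large bounding box
#' against each of the 2K half-planes, which is robust when some
#' boundaries are inactive (redundant); vertices are returned in
#' counter-clockwise order starting from the smallest centroid angle.
#'
#' @param bands A list of [directional_band()] objects covering a
#'   direction grid.
#' @return Object of class \code{"convex_region"} with components
#'   \code{vertices} (ordered m x 2 matrix), \code{halfplanes} (2K x 3
#'   matrix of constraints \eqn{a x + b y \le c}), \code{alpha_dir},
#'   \code{n_directions}.
#' @examples
#' pts <- cbind(rnorm(200), rnorm(200))
#' bands <- lapply(direction_grid(8), directional_band,
#'                 points = pts, alpha_dir = 0.1)
#' region_from_bands(bands)
#' @export
region_from_bands <- function(bands) {
  if (inherits(bands, "directional_band")) bands <- list(bands)
  stopifnot(length(bands) >= 1L,
            all(vapply(bands, inherits, logical(1), "directional_band")))
  K <- length(bands)
  theta <- vapply(bands, `[[`, numeric(1), "theta")
  B_l <- vapply(bands, `[[`, numeric(1), "B_l")
  B_u <- vapply(bands, `[[`, numeric(1), "B_u")
  if (any(!is.finite(c(B_l, B_u)))) stop("band boundaries must be finite")
  if (K < 2L)
    warning("fewer than 2 directions: the band intersection is an ",
            "unbounded slab; returning a truncated polygon")
  ## constraints: -sin(th)*x + cos(th)*y <= B_u  and  >= B_l
  hp <- rbind(
    cbind(-sin(theta),  cos(theta),  B_u),
    cbind( sin(theta), -cos(theta), -B_l))
  colnames(hp) <- c("a", "b", "c")
  M <- max(abs(c(B_l, B_u)), 1e-12)
  half <- 1e3 * M
  box <- rbind(c(-half, -half), c(half, -half), c(half, half), c(-half, half))
  verts <- box
  for (i in seq_len(nrow(hp))) {
    verts <- clip_halfplane(verts, hp[i, 1L], hp[i, 2L], hp[i, 3L])
    if (nrow(verts) == 0L)
      stop("the band intersection is empty; check the supplied boundaries")
  }
  verts <- canonical_vertices(verts)
  scale <- max(1, max(abs(verts)))
  if (nrow(verts) >= 1L && polygon_area(verts) < 1e-12 * scale^2)
    warning("degenerate (zero-area) region: the points may be collinear")
  new_convex_region(
    vertices = verts, halfplanes = hp,
    alpha_dir = bands[[1L]]$alpha_dir, n_directions = K)
}

polygon_area <- function(verts) {
  n <- nrow(verts)
  if (is.null(n) || n < 3L) return(0)
  x <- verts[, 1L]; y <- verts[, 2L]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Area of a convex region
#'
#' Shoelace area of the region's vertex polygon.
#'
#' @param region A \code{"convex_region"}.
#' @return Nonnegative area.
#' @export
region_area <- function(region) {
  stopifnot(inherits(region, "convex_region"))
  polygon_area(region$vertices)
}

#' Point-in-region membership test
#'
#' Tests whether points fall inside or on the boundary of a convex region.
#' For regions built from directional bands the stored half-plane
#' constraints are evaluated directly, so membership is exactly the
#' conjunction of all 2K directional band constraints; for other regions
#' (ellipse, peeled hull) the convex polygon edge test is used.  Points on
#' the boundary count as inside.
#'
#' @param region A \code{"convex_region"}.
#' @param points A point set (or a single \code{c(x, y)} pair).
#' @param tol Absolute slack allowed on each constraint, to absorb
#'   floating-point rounding on the boundary; default \code{1e-9} scaled
#'   by the region's magnitude.
#' @return Logical vector, one entry per point.
#' @export
region_contains <- function(region, points, tol = NULL) {
  stopifnot(inherits(region, "convex_region"))
  if (is.numeric(points) && is.null(dim(points)) && length(points) == 2L)
    points <- matrix(points, 1L, 2L)
  points <- as_points(points)
  if (!is.null(region$halfplanes)) {
    hp <- region$halfplanes
    if (is.null(tol)) tol <- 1e-9 * max(1, max(abs(hp[, 3L])))
    inside <- rep(TRUE, nrow(points))
    for (i in seq_len(nrow(hp))) {
      inside <- inside &
        (hp[i, 1L] * points[, 1L] + hp[i, 2L] * points[, 2L] <= hp[i, 3L] + tol)
    }
    return(inside)
  }
  verts <- region$vertices
  nv <- nrow(verts)
  if (nv < 3L) return(rep(FALSE, nrow(points)))
  if (is.null(tol)) tol <- 1e-9 * max(1, max(abs(verts)))
  inside <- rep(TRUE, nrow(points))
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1L else i + 1L
    ex <- verts[j, 1L] - verts[i, 1L]
    ey <- verts[j, 2L] - verts[i, 2L]
    ## CCW polygon: interior is to the left of each edge
    cr <- ex * (points[, 2L] - verts[i, 2L]) - ey * (points[, 1L] - verts[i, 1L])
    inside <- inside & (cr >= -tol * max(1, abs(ex) + abs(ey)))
  }
  inside
}

#' @export
print.convex_region <- function(x, ...) {
  cat(sprintf("Convex confidence region (%s)\n", x$method))
  cat(sprintf("  vertices: %d\n", nrow(x$vertices)))
  if (!is.na(x$n_directions))
    cat(sprintf("  directions: %d, per-direction level: %.6g\n",
                x$n_directions, x$alpha_dir))
  if (!is.null(x$alpha_e))
    cat(sprintf("  realized alpha: %.6g (nominal %.6g, alpha_t* %.6g)\n",
                x$alpha_e, x$alpha_d, x$alpha_t_star))
  cat(sprintf("  area: %.6g\n", region_area(x)))
  invisible(x)
}

#' @export
plot.convex_region <- function(x, add = FALSE, points = NULL, ...) {
  v <- rbind(x$vertices, x$vertices[1L, , drop = FALSE])
  if (!add) {
    lim_x <- range(v[, 1L]); lim_y <- range(v[, 2L])
    if (!is.null(points)) {
      points <- as_points(points)
      lim_x <- range(lim_x, points[, 1L]); lim_y <- range(lim_y, points[, 2L])
    }
    graphics::plot(NA, xlim = lim_x, ylim = lim_y, xlab = "x", ylab = "y")
    if (!is.null(points))
      graphics::points(points, pch = 16, cex = 0.4, col = "grey60")
  }
  graphics::lines(v, ...)
  invisible(x)
}
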