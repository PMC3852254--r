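#' Coverage-discrepancy study over designs, methods and levels
#'
#' For each simulation design and replicate, draws one sample and, for
#' every requested method and nominal level, builds the region and
#' records the realized exclusion rate (the in-sample proportion of the
#' sample outside the region) and its discrepancy from the nominal level.
#' This is the harness behind coverage-discrepancy plots: discrepancy as
#' a function of the nominal level, per design and method.
#'
#' Per-cell method failures are recorded as \code{NA} rows (with the
#' error message) rather than aborting the grid.  Replicate r of design d
#' reuses the design with seed \code{design$seed + r - 1}, so the whole
#' grid is reproducible from the design seeds.
#'
#' @param designs A [sim_design()] or list of them.
#' @param methods Character subset of \code{c("distfree", "ellipse",
#'   "peel")}.
#' @param alphas Numeric vector of nominal levels in (0, 1); the default
#'   is the seven-level grid 0.005, 0.01, 0.025, 0.05, 0.1, 0.2, 0.5.
#' @param reps Replicates per design (default 1).
#' @param K Directions for the distribution-free region (default 72).
#' @param tol Calibration tolerance passed to [calibrate_alpha()].
#' @return A data frame with one row per (design, replicate, method,
#'   alpha): columns \code{design}, \code{n}, \code{r_xy}, \code{seed},
#'   \code{replicate}, \code{method}, \code{alpha_nominal},
#'   \code{alpha_realized}, \code{discrepancy}, \code{error}.
#' @examples
#' d <- sim_design("normal", n = 400, r_xy = 0.5, seed = 3)
#' head(coverage_discrepancy(d, "ellipse", alphas = c(0.05, 0.5)))
#' @export
coverage_discrepancy <- function(designs,
                                 methods = c("distfree", "ellipse", "peel"),
                                 alphas = c(0.005, 0.01, 0.025, 0.05,
                                            0.1, 0.2, 0.5),
                                 reps = 1L, K = 72L, tol = NULL) {
  if (inherits(designs, "sim_design")) designs <- list(designs)
  stopifnot(all(vapply(designs, inherits, logical(1), "sim_design")))
  methods <- match.arg(methods, several.ok = TRUE)
  if (any(alphas <= 0 | alphas >= 1)) stop("alphas must lie in (0, 1)")
  rows <- list()
  for (design in designs) {
    for (rep_i in seq_len(reps)) {
      des_r <- design
      des_r$seed <- design$seed + rep_i - 1L
      pts <- sample_points(des_r)
      for (method in methods) {
        for (a in alphas) {
          realized <- NA_real_; err <- NA_character_
          res <- tryCatch({
            region <- switch(method,
              distfree = confidence_region(pts, alpha_d = a, K = K, tol = tol),
              ellipse  = ellipse_region(pts, alpha = a),
              peel     = hull_peel_region(pts, alpha = a))
            realized_alpha(pts, region)
          }, error = function(e) e)
          if (inherits(res, "error")) err <- conditionMessage(res)
          else realized <- res
          rows[[length(rows) + 1L]] <- data.frame(
            design = des_r$design, n = des_r$n, r_xy = des_r$r_xy,
            seed = des_r$seed, replicate = rep_i, method = method,
            alpha_nominal = a, alpha_realized = realized,
            discrepancy = realized - a, error = err,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Chi-square test of coverage deviation
#'
#' One-degree-of-freedom goodness-of-fit test of the observed
#' outside/inside split against the nominal exclusion probability
#' \code{alpha0}: \eqn{X^2 = \sum (O - E)^2 / E} over the two cells with
#' expected counts \eqn{n\alpha_0} and \eqn{n(1-\alpha_0)}; the p-value
#' is the chi-square(1) upper tail.  No continuity correction is applied.
#'
#' @param m_outside Observed number of points outside the region.
#' @param n Total number of points (positive).
#' @param alpha0 Nominal exclusion probability in (0, 1).
#' @return List with \code{statistic}, \code{p_value}, \code{expected}.
#' @examples
#' chisq_coverage_test(600, 10000, 0.05)$statistic  # about 21.05
#' @export
chisq_coverage_test <- function(m_outside, n, alpha0) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive count")
  if (m_outside < 0 || m_outside > n)
    stop("m_outside must lie between 0 and n")
  if (alpha0 <= 0 || alpha0 >= 1) stop("alpha0 must lie in (0, 1)")
  expected <- c(outside = n * alpha0, inside = n * (1 - alpha0))
  observed <- c(m_outside, n - m_outside)
  statistic <- sum((observed - expected)^2 / expected)
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
       expected = expected)
}

#' Bootstrap a point cloud of paired statistics
#'
#' Case-resamples the rows of \code{data} with replacement (resample size
#' = original size), evaluates a bivariate statistic on each resample,
#' and returns the B pairs as a point set ready for
#' [confidence_region()].  A resample on which the statistic fails (or
#' returns non-finite values) is redrawn; the redraw count is recorded.
#'
#' @param data A data frame or matrix of observations (rows = cases).
#' @param statistic Function mapping a resampled data object to a numeric
#'   pair \code{c(x, y)}.
#' @param B Number of bootstrap replicates (at least 100).
#' @param seed Integer RNG seed.
#' @param max_redraws Cap on redrawn resamples (default \code{B}).
#' @return A B x 2 point matrix with attribute \code{n_redrawn}.
#' @examples
#' d <- data.frame(u = rnorm(30), v = rnorm(30))
#' bp <- bootstrap_pairs(d, function(s) c(mean(s$u), mean(s$v)),
#'                       B = 200, seed = 4)
#' @export
bootstrap_pairs <- function(data, statistic, B = 10000L, seed = 1L,
                            max_redraws = NULL) {
  B <- as.integer(B)
  if (is.na(B) || B < 100L) stop("B must be at least 100")
  nr <- nrow(data)
  if (is.null(nr) || nr < 1L) stop("data must have at least one row")
  if (is.null(max_redraws)) max_redraws <- B
  with_private_seed(seed, {
    out <- matrix(NA_real_, B, 2L)
    n_redrawn <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(nr, nr, replace = TRUE)
        resample <- if (is.matrix(data)) data[idx, , drop = FALSE]
                    else data[idx, , drop = FALSE]
        val <- tryCatch(statistic(resample), error = function(e) NULL)
        ok <- is.numeric(val) && length(val) == 2L && all(is.finite(val))
        if (ok) { out[b, ] <- val; break }
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > max_redraws)
          stop("too many resamples failed; check the statistic")
      }
    }
    colnames(out) <- c("x", "y")
    attr(out, "n_redrawn") <- n_redrawn
    attr(out, "seed") <- seed
    out
  })
}

#' Plot coverage-discrepancy curves
#'
#' Discrepancy (realized minus nominal level) against the nominal level,
#' one curve per method, faceted by design label.
#'
#' @param records Output of [coverage_discrepancy()].
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the records.
#' @export
plot_coverage_discrepancy <- function(records, ...) {
  stopifnot(is.data.frame(records))
  methods <- unique(records$method)
  agg <- stats::aggregate(
    discrepancy ~ alpha_nominal + method, data = records, FUN = mean)
  alphas <- sort(unique(agg$alpha_nominal))
  mat <- sapply(methods, function(m)
    agg$discrepancy[agg$method == m][order(agg$alpha_nominal[agg$method == m])])
  graphics::matplot(alphas, mat, type = "b", pch = seq_along(methods),
                    xlab = "nominal alpha", ylab = "discrepancy", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", legend = methods, pch = seq_along(methods),
                   col = seq_along(methods), bty = "n")
  invisible(records)
}
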