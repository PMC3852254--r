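#' Specify a bivariate simulation design
#'
#' Describes one of the three seeded bivariate sampling designs used to
#' exercise the region constructors: \code{"normal"} (bivariate normal),
#' \code{"noncentral_f"} (each margin exactly noncentral
#' \eqn{F(\nu_1, \nu_2, \lambda)}, cross-dependence through a Gaussian
#' copula tuned to a target Pearson correlation), and
#' \code{"normal_mixture"} (a two-component mixture of bivariate
#' normals).
#'
#' @param design One of \code{"normal"}, \code{"noncentral_f"},
#'   \code{"normal_mixture"}.
#' @param n Sample size.
#' @param r_xy Target Pearson cross-correlation, \eqn{|r| < 1}.
#' @param seed Integer RNG seed; identical designs yield bit-identical
#'   samples.
#' @param mean,sd Normal design: mean vector and marginal standard
#'   deviations (defaults \code{c(0, 0)} and \code{c(1, 1)}).
#' @param df1,df2,ncp Noncentral-F design: numerator/denominator degrees
#'   of freedom and noncentrality per margin (defaults 5, 10, 3).
#' @param weight,mean1,mean2,sd1,sd2 Mixture design: probability of
#'   component 1 and the component mean vectors / marginal standard
#'   deviations (defaults: weight 0.5, means \code{c(0, 0)} and
#'   \code{c(4, 4)}, unit standard deviations; each component uses the
#'   common correlation \code{r_xy}).
#' @return Object of class \code{"sim_design"}.
#' @examples
#' d <- sim_design("normal", n = 500, r_xy = 0.5, seed = 1)
#' pts <- sample_points(d)
#' cor(pts[, 1], pts[, 2])
#' @export
sim_design <- function(design = c("normal", "noncentral_f", "normal_mixture"),
                       n, r_xy = 0, seed = 1L,
                       mean = c(0, 0), sd = c(1, 1),
                       df1 = 5, df2 = 10, ncp = 3,
                       weight = 0.5, mean1 = c(0, 0), mean2 = c(4, 4),
                       sd1 = c(1, 1), sd2 = c(1, 1)) {
  design <- match.arg(design)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be a positive integer")
  if (!is.finite(r_xy) || abs(r_xy) >= 1) stop("|r_xy| must be < 1")
  params <- switch(design,
    normal = {
      if (any(sd <= 0)) stop("marginal standard deviations must be positive")
      list(mean = mean, sd = sd)
    },
    noncentral_f = {
      if (df1 <= 0 || df2 <= 0) stop("degrees of freedom must be positive")
      if (ncp < 0) stop("the noncentrality parameter must be nonnegative")
      list(df1 = df1, df2 = df2, ncp = ncp)
    },
    normal_mixture = {
      if (weight <= 0 || weight >= 1) stop("mixing weight must be in (0, 1)")
      if (any(c(sd1, sd2) <= 0))
        stop("marginal standard deviations must be positive")
      list(weight = weight, mean1 = mean1, mean2 = mean2, sd1 = sd1, sd2 = sd2)
    })
  structure(list(design = design, n = n, r_xy = r_xy, seed = as.integer(seed),
                 params = params),
            class = "sim_design")
}

## Cholesky factor of the 2x2 correlation-structured covariance.
cov2_chol <- function(sd, r) {
  S <- matrix(c(sd[1L]^2, r * sd[1L] * sd[2L],
                r * sd[1L] * sd[2L], sd[2L]^2), 2L, 2L)
  tryCatch(chol(S), error = function(e)
    stop("the implied covariance matrix is not positive definite"))
}

## Run code under a private RNG stream, restoring the caller's state.
with_private_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## AR(1)-filter each column of an iid standard-normal matrix, preserving
## the unit stationary marginal variance (x_1 = z_1, then
## x_t = phi x_{t-1} + sqrt(1 - phi^2) z_t).
ar1_filter <- function(z, phi) {
  if (phi == 0) return(z)
  scale <- sqrt(1 - phi^2)
  apply(z, 2L, function(col) {
    x <- numeric(length(col))
    x[1L] <- col[1L]
    for (t in seq_along(col)[-1L]) x[t] <- phi * x[t - 1L] + scale * col[t]
    x
  })
}

## Solve for the latent Gaussian-copula correlation that makes the
## noncentral-F margins hit the target Pearson correlation.  Uses common
## random numbers (one fixed internal quasi-sample) so the map
## rho -> cor is smooth and monotone; errors with the feasible range when
## the target is unattainable.
.rho_cache <- new.env(parent = emptyenv())

solve_latent_rho <- function(r_target, df1, df2, ncp, m = 20000L) {
  if (r_target == 0) return(0)
  key <- paste(r_target, df1, df2, ncp, m, sep = "|")
  if (!is.null(.rho_cache[[key]])) return(.rho_cache[[key]])
  z <- with_private_seed(905157L, matrix(stats::rnorm(2L * m), m, 2L))
  f_margin <- function(u) stats::qf(u, df1 = df1, df2 = df2, ncp = ncp)
  x <- f_margin(stats::pnorm(z[, 1L]))
  cor_at <- function(rho) {
    y <- f_margin(stats::pnorm(rho * z[, 1L] + sqrt(1 - rho^2) * z[, 2L]))
    stats::cor(x, y)
  }
  lim <- 0.9999
  r_max <- cor_at(lim); r_min <- cor_at(-lim)
  if (r_target > r_max || r_target < r_min)
    stop(sprintf(
      "target correlation %.3f is unattainable for F(%g, %g, ncp = %g): feasible range is [%.3f, %.3f]",
      r_target, df1, df2, ncp, r_min, r_max))
  rho <- stats::uniroot(function(rho) cor_at(rho) - r_target,
                        interval = c(-lim, lim), tol = 1e-6)$root
  .rho_cache[[key]] <- rho
  rho
}

## Core transform: map an n x 2 iid (or AR(1)-filtered) standard-normal
## matrix, plus pre-drawn mixture labels, into the design's distribution.
transform_latent <- function(design, z, labels = NULL) {
  p <- design$params
  r <- design$r_xy
  switch(design$design,
    normal = {
      L <- cov2_chol(p$sd, r)
      sweep(z %*% L, 2L, p$mean, `+`)
    },
    noncentral_f = {
      rho <- solve_latent_rho(r, p$df1, p$df2, p$ncp)
      z2 <- cbind(z[, 1L], rho * z[, 1L] + sqrt(1 - rho^2) * z[, 2L])
      u <- stats::pnorm(z2)
      cbind(stats::qf(u[, 1L], p$df1, p$df2, ncp = p$ncp),
            stats::qf(u[, 2L], p$df1, p$df2, ncp = p$ncp))
    },
    normal_mixture = {
      L1 <- cov2_chol(p$sd1, r)
      L2 <- cov2_chol(p$sd2, r)
      out1 <- sweep(z %*% L1, 2L, p$mean1, `+`)
      out2 <- sweep(z %*% L2, 2L, p$mean2, `+`)
      ifelse(matrix(labels, nrow(z), 2L), out1, out2)
    })
}

draw_points <- function(design, phi = 0) {
  with_private_seed(design$seed, {
    labels <- NULL
    if (design$design == "normal_mixture")
      labels <- stats::runif(design$n) < design$params$weight
    z <- matrix(stats::rnorm(2L * design$n), design$n, 2L)
    z <- ar1_filter(z, phi)
    pts <- transform_latent(design, z, labels)
    colnames(pts) <- c("x", "y")
    attr(pts, "seed") <- design$seed
    attr(pts, "design") <- design$design
    if (phi != 0) attr(pts, "phi") <- phi
    pts
  })
}

#' Draw a sample from a simulation design
#'
#' Seeded sampler dispatching on the design type; identical
#' \code{sim_design} objects yield bit-identical samples.
#'
#' @param design A [sim_design()].
#' @return An n x 2 point matrix with attributes recording the seed and
#'   design type.
#' @export
sample_points <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  draw_points(design, phi = 0)
}

#' Draw a serially dependent sample from a simulation design
#'
#' As [sample_points()], but injects AR(1) dependence at lag-1
#' coefficient \code{phi} into each margin's latent driving noise before
#' the design's marginal transform, preserving the stationary marginal
#' variance.  With \code{phi = 0} this reproduces [sample_points()]
#' exactly (same seed, same draws).
#'
#' @param design A [sim_design()].
#' @param phi AR(1) coefficient, \eqn{|\phi| < 1}.
#' @return An n x 2 point matrix.
#' @export
sample_ar1 <- function(design, phi) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.finite(phi) || abs(phi) >= 1) stop("|phi| must be < 1")
  draw_points(design, phi = phi)
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("Simulation design: %s (n = %d, r_xy = %g, seed = %d)\n",
              x$design, x$n, x$r_xy, x$seed))
  utils::str(x$params, give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
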