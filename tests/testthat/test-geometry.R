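test_that("signed distances match the perpendicular-distance formula", {
  expect_equal(signed_distances(rbind(c(2, 3)), 0), 3)
  expect_equal(signed_distances(rbind(c(1, 1)), pi / 4), 0)
  # |y - x| / sqrt(2) for the 45-degree line, with sign above the line
  expect_equal(signed_distances(rbind(c(0, 2)), pi / 4), sqrt(2))
  # vectorized over points, and sign flips below the line
  pts <- rbind(c(1, 2), c(3, -1), c(-2, 0.5))
  th <- 1.1
  expect_equal(signed_distances(pts, th),
               pts[, 2] * cos(th) - pts[, 1] * sin(th))
  expect_error(signed_distances(rbind(c(1, NA)), 0), "finite")
  expect_error(signed_distances(rbind(c(1, 1)), pi), "\\[0, pi\\)")
})

test_that("empirical quantile interpolates between bracketing order statistics", {
  expect_equal(empirical_quantile(c(5, 5, 5), 0.37), 5)
  expect_equal(empirical_quantile(1:5, 0), 1)
  expect_equal(empirical_quantile(1:5, 1), 5)
  expect_equal(empirical_quantile(1:100, 0.5), 50.5)
  # agrees with a hand-rolled rank-interpolation oracle on random data
  set.seed(5)
  x <- rexp(57)
  for (p in c(0.025, 0.1, 0.5, 0.9, 0.975))
    expect_equal(empirical_quantile(x, p), oracle_quantile(x, p))
  expect_error(empirical_quantile(numeric(0), 0.5), "nonempty")
  expect_error(empirical_quantile(c(1, NaN), 0.5), "NA")
  expect_error(empirical_quantile(1:5, 1.2), "\\[0, 1\\]")
})

test_that("directional band realizes its per-direction level", {
  pts <- bvn_cloud(1000, seed = 11)
  b <- directional_band(pts, 0.7, 0.05)
  # out-of-band count against an independent sort-and-count oracle
  d <- pts[, 2] * cos(0.7) - pts[, 1] * sin(0.7)
  lo <- oracle_quantile(d, 0.025); hi <- oracle_quantile(d, 0.975)
  expect_identical(b$S_theta, which(d < lo | d > hi))
  expect_equal(b$m_theta, length(b$S_theta))
  expect_lte(abs(b$m_theta / 1000 - 0.05), 2 / 1000)
  expect_lte(b$B_l, b$B_u)
})

test_that("band boundaries are symmetric for symmetric distances and wide bands exclude nothing", {
  # exactly sign-symmetric point cloud
  base <- bvn_cloud(500, seed = 2)
  pts <- rbind(base, -base)
  b <- directional_band(pts, 1.2, 0.1)
  expect_equal(b$B_l, -b$B_u, tolerance = 1e-12)
  # alpha small enough that the band spans the whole range: with tied
  # extreme distances the interpolated boundary sits on the extremes and
  # boundary points count as inside
  dup <- rbind(base, base)
  tiny <- directional_band(dup, 1.2, 1e-6)
  expect_identical(tiny$m_theta, 0L)
  # degenerate: all distances equal -> zero width, warned
  line_pts <- cbind(seq_len(10), rep(2, 10))   # on y = 2
  expect_warning(bb <- directional_band(line_pts, 0, 0.1), "zero width")
  expect_equal(bb$B_l, bb$B_u)
})

test_that("axis-aligned slabs intersect to the expected square", {
  mk_band <- function(theta, lo, hi)
    structure(list(theta = theta, alpha_dir = 0.1, B_l = lo, B_u = hi,
                   m_theta = 0L, S_theta = integer(0), n = 0L),
              class = "directional_band")
  reg <- region_from_bands(list(mk_band(0, -1, 1), mk_band(pi / 2, -1, 1)))
  v <- reg$vertices
  expect_equal(nrow(v), 4L)
  # theta = 0 bounds y, theta = pi/2 bounds x (distance is -x there)
  expect_equal(sort(v[, 1]), c(-1, -1, 1, 1))
  expect_equal(sort(v[, 2]), c(-1, -1, 1, 1))
  expect_error(
    region_from_bands(list(mk_band(0, 10, 11), mk_band(0, -11, -10))),
    "empty")
})

test_that("polygon membership is the conjunction of all band constraints", {
  pts <- bvn_cloud(800, r = 0.6, seed = 31)
  grid <- direction_grid(12)
  bands <- lapply(as.numeric(grid), directional_band,
                  points = pts, alpha_dir = 0.1)
  reg <- region_from_bands(bands)
  # every data point: in-polygon <=> inside all bands
  in_poly <- region_contains(reg, pts)
  in_bands <- brute_band_inside(bands, pts[, 1], pts[, 2])
  expect_identical(in_poly, in_bands)
  # vertex count bounded by the number of boundary lines
  expect_lte(nrow(reg$vertices), 2 * attr(grid, "K"))
})

test_that("adjacent-boundary crossovers reproduce polygon vertices", {
  pts <- bvn_cloud(400, r = 0.3, seed = 7)
  K <- 10
  grid <- direction_grid(K)
  bands <- lapply(as.numeric(grid), directional_band,
                  points = pts, alpha_dir = 0.2)
  reg <- region_from_bands(bands)
  v <- reg$vertices
  # for each polygon vertex, find its two active boundary lines and check
  # it solves the 2x2 adjacent-crossover system exactly
  theta <- vapply(bands, `[[`, numeric(1), "theta")
  matched <- 0L
  for (i in seq_len(nrow(v))) {
    d <- v[i, 2] * cos(theta) - v[i, 1] * sin(theta)
    act <- which(abs(d - vapply(bands, `[[`, numeric(1), "B_u")) < 1e-8 |
                 abs(d - vapply(bands, `[[`, numeric(1), "B_l")) < 1e-8)
    if (length(act) == 2) {
      c1 <- d[act[1]]; c2 <- d[act[2]]
      A <- rbind(c(-sin(theta[act[1]]), cos(theta[act[1]])),
                 c(-sin(theta[act[2]]), cos(theta[act[2]])))
      xy <- solve(A, c(c1, c2))
      expect_equal(unname(v[i, ]), unname(xy), tolerance = 1e-8)
      matched <- matched + 1L
    }
  }
  expect_gte(matched, 3L)  # generic vertices have exactly two active lines
})

test_that("region membership agrees with a ray-casting oracle off-edge", {
  pts <- bvn_cloud(600, r = -0.4, seed = 13)
  reg <- confidence_region(pts, alpha_d = 0.1, K = 24)
  set.seed(99)
  qx <- runif(10000, -4, 4); qy <- runif(10000, -4, 4)
  got <- region_contains(reg, cbind(qx, qy))
  want <- ray_cast_inside(reg$vertices, qx, qy)
  # exclude points too close to the boundary for the oracle to be exact
  hp <- reg$halfplanes
  gap <- apply(abs(hp[, 1] %o% qx + hp[, 2] %o% qy - hp[, 3]), 2, min)
  off_edge <- gap > 1e-6
  expect_gt(sum(off_edge), 9900)
  expect_identical(got[off_edge], want[off_edge])
  # trivial cases
  expect_true(region_contains(reg, colMeans(reg$vertices)))
  expect_false(region_contains(reg, c(100, 100)))
})

test_that("constructed regions are convex with canonically ordered vertices", {
  for (seed in 1:4) {
    pts <- bvn_cloud(300, r = 0.5, seed = seed)
    reg <- confidence_region(pts, alpha_d = 0.2, K = 16)
    v <- reg$vertices
    hull <- grDevices::chull(v)
    expect_identical(sort(hull), seq_len(nrow(v)))  # all vertices extreme
    # counter-clockwise: positive shoelace signed area
    j <- c(2:nrow(v), 1)
    expect_gt(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2, 0)
  }
})

test_that("regions are translation equivariant", {
  pts <- bvn_cloud(500, r = 0.2, seed = 21)
  shift <- c(3.5, -1.25)
  r1 <- confidence_region(pts, alpha_d = 0.1, K = 20)
  r2 <- confidence_region(sweep(pts, 2, shift, `+`), alpha_d = 0.1, K = 20)
  expect_equal(sweep(r1$vertices, 2, shift, `+`), r2$vertices,
               tolerance = 1e-9)
})

test_that("rotating data by the grid spacing rotates the region by the same angle", {
  pts <- bvn_cloud(500, r = 0.7, seed = 22)
  K <- 18
  delta <- pi / K
  R <- rbind(c(cos(delta), -sin(delta)), c(sin(delta), cos(delta)))
  r1 <- confidence_region(pts, alpha_d = 0.1, K = K)
  r2 <- confidence_region(pts %*% t(R), alpha_d = 0.1, K = K)
  rotated <- canonical_vertices(r1$vertices %*% t(R))
  expect_equal(unname(r2$vertices), unname(rotated), tolerance = 1e-8)
})

test_that("regions at smaller alpha contain regions at larger alpha", {
  pts <- bvn_cloud(400, r = 0.4, seed = 23)
  grid <- direction_grid(16)
  for (pair in list(c(0.02, 0.1), c(0.1, 0.3), c(0.05, 0.5))) {
    bands_lo <- lapply(as.numeric(grid), directional_band,
                       points = pts, alpha_dir = pair[1])
    bands_hi <- lapply(as.numeric(grid), directional_band,
                       points = pts, alpha_dir = pair[2])
    wide <- region_from_bands(bands_lo)
    narrow <- region_from_bands(bands_hi)
    expect_true(all(region_contains(wide, narrow$vertices, tol = 1e-9)))
  }
})

test_that("region construction rejects too-small or degenerate input", {
  expect_error(as_points(rbind(c(1, 2)), min_n = 3), "at least 3")
  expect_warning(
    reg <- region_from_bands(lapply(
      as.numeric(direction_grid(4)),
      function(th) suppressWarnings(
        directional_band(cbind(1:10, rep(0, 10)), th, 0.1)))),
    "collinear|zero")
  expect_equal(region_area(reg), 0, tolerance = 1e-12)
})
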