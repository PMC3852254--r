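# dqcr — distribution-free confidence regions for two parameters

`dqcr` builds nonparametric joint confidence regions for a pair of
parameters directly from a point cloud — typically `B` bootstrap
replicates of two estimates — with no assumption about the sampling
distribution's shape.  It is aimed at the situations where such clouds
arise in biology and genetics: joint regions for regression
coefficients, for principal-component scores of individuals or
populations, for genotype and environment scores in biplots.

## The method

For a reference line through the origin at angle θ, every observation
(xᵢ, yᵢ) has a signed perpendicular distance

    dᵢ(θ) = yᵢ cos θ − xᵢ sin θ .

At a per-direction level α_t, the empirical α_t/2 and 1−α_t/2 quantiles
of the dᵢ define two boundary lines parallel to the reference line: a
slab holding about 1−α_t of the points.  Intersecting these slabs over
K equally spaced directions on [0, π) gives a convex polygon that
follows the actual shape of the cloud.

Because the polygon intersects K simultaneous bands, at α_t = α_d it
excludes **more** than a fraction α_d of the points.  `dqcr` therefore
calibrates: bisection finds the per-direction level α_t\* ≤ α_d whose
polygon excludes a fraction of points matching the desired α_d (the
realized level α_e).  Two classical baselines — the normal-theory
ellipse and convex hull peeling — plus seeded simulators (bivariate
normal, noncentral-F via a Gaussian copula, normal mixture, optional
AR(1) serial dependence) and a coverage-discrepancy harness round out
the package.

## Worked example

A bimodal cloud (mixture of two bivariate normals) is the stress case
for ellipse-shaped regions:

```r
library(dqcr)
d   <- sim_design("normal_mixture", n = 5000, r_xy = 0.5, seed = 2024)
pts <- sample_points(d)

cal <- calibrate_alpha(pts, alpha_d = 0.05, grid = direction_grid(72))
cal
#> Calibrated distribution-free confidence region
#>   n = 5000 points, K = 72 directions
#>   desired alpha_d          : 0.05
#>   solved alpha_t*          : 0.0124025
#>   realized alpha_e         : 0.05
#>   uncalibrated discrepancy : +0.1134
#>   bisection iterations     : 42
```

Reading the report: at the uncalibrated per-direction level 0.05 the
polygon would exclude 16.3% of the points (discrepancy +0.1134) — the
multiplicity inflation of 72 simultaneous bands.  Calibration shrinks
the per-direction level to α_t\* = 0.0124, whose polygon excludes
exactly 5.0% of the cloud.

The parametric ellipse on the same cloud misses the target:

```r
e <- ellipse_region(pts, alpha = 0.05)
realized_alpha(pts, e)
#> [1] 0.0302
region_area(cal$region); region_area(e)
#> [1] 33.8
#> [1] 42.1
chisq_coverage_test(sum(!region_contains(e, pts)), 5000, 0.05)$statistic
#> [1] 41.27   # chi-square(1), p = 1.3e-10: significant coverage bias
```

The ellipse excludes only 3.0% instead of 5% (it inflates to cover the
gap between the two modes), and the deviation is highly significant by
the one-df chi-square coverage test.  The calibrated polygon is 20%
smaller *and* exact on the realized level.

For real data, `bootstrap_pairs()` produces the cloud:

```r
cloud <- bootstrap_pairs(mydata, function(s) coef(lm(y ~ x1 + x2, s))[2:3],
                         B = 10000, seed = 1)
region <- confidence_region(cloud, alpha_d = 0.05, K = 100)
write_region(region, "region.csv")          # vertex_index, x, y
write_region(region, "region.wkt", "wkt")   # WKT POLYGON
```

A thin command-line wrapper with subcommands `region`, `simulate`,
`evaluate` and `test-coverage` is installed under `inst/cli/dqcr`.

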