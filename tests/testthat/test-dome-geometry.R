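test_that("distance-to-radius conversion matches the printed pairs", {
  expect_equal(radius_from_distance(9)$r, 6.062, tolerance = 1e-3)
  expect_equal(radius_from_distance(19)$r, 11.836, tolerance = 1e-3)
  expect_equal(radius_from_distance(24)$r, 14.722, tolerance = 1e-3)
  expect_equal(radius_from_distance(34)$r, 20.496, tolerance = 1e-3)
  expect_equal(radius_from_distance(19.5)$r, 12.124, tolerance = 1e-3)
  expect_equal(radius_from_distance(0)$r, 1.5 / sqrt(3))
  expect_equal(radius_from_distance(10)$r_error, 2.3 / sqrt(3))
  expect_error(radius_from_distance(-1), "non-negative")
  # strictly increasing and affine
  d <- seq(0, 40, by = 0.5)
  r <- radius_from_distance(d)$r
  expect_true(all(diff(r) > 0))
  expect_equal(diff(r) / diff(d), rep(1 / sqrt(3), length(d) - 1))
})

test_that("spherical-cap curvature follows R = (r^2 + h^2) / (2h)", {
  expect_equal(curvature_radius(6, 5.5), 6.0227, tolerance = 1e-4)
  expect_equal(curvature_radius(20, 1), 200.5)
  # hemisphere: R = r when h = r; that is also the minimum over h
  expect_equal(curvature_radius(7, 7), 7)
  h <- seq(0.5, 20, by = 0.1)
  expect_equal(min(curvature_radius(7, h)), 7, tolerance = 1e-3)
  expect_true(all(curvature_radius(7, h[h <= 7]) >= 7 - 1e-9))
  expect_error(curvature_radius(6, 0), "positive")
  expect_error(curvature_radius(6, -1), "positive")
})

test_that("median curvature integrates the dome-height uncertainty", {
  # r = 12 over h in (0, 5]: R(h) decreases on the range, so the median is
  # R at the midpoint height 2.5
  mc <- median_curvature(12, c(0, 5), n_samples = 2e5, seed = 1)
  expect_equal(mc$median, curvature_radius(12, 2.5), tolerance = 0.01)
  expect_lt(mc$interval[1], mc$median)
  expect_gt(mc$interval[2], mc$median)
  # monotonicity argument holds whenever r >= h_max
  mc2 <- median_curvature(5, c(0, 5), n_samples = 2e5, seed = 2)
  expect_equal(mc2$median, curvature_radius(5, 2.5), tolerance = 0.02)
  # degenerate range: median equals the closed form exactly in the limit
  mc3 <- median_curvature(12, c(2.5 - 1e-9, 2.5), n_samples = 100, seed = 3)
  expect_equal(mc3$median, curvature_radius(12, 2.5), tolerance = 1e-6)
  # r uncertainty widens the interval (compared away from the h -> 0
  # divergence, where the tail percentile is Monte Carlo dominated)
  mcA <- median_curvature(12, c(2, 5), n_samples = 2e4, seed = 4)
  mcB <- median_curvature(12, c(2, 5), n_samples = 2e4, r_sd = 1.3, seed = 4)
  expect_gt(diff(mcB$interval), diff(mcA$interval))
  expect_identical(median_curvature(12, seed = 9),
                   median_curvature(12, seed = 9))
})

test_that("dome_geometry chains the conversions", {
  g <- dome_geometry(9, h = 5.5, h_range = c(0, 5), seed = 5)
  expect_equal(g$r, radius_from_distance(9)$r)
  expect_equal(g$R, curvature_radius(g$r, 5.5))
  expect_equal(g$R_median, median_curvature(g$r, c(0, 5), seed = 5)$median)
  expect_true(is.finite(g$R_median) && g$R_median > 0)
})

test_that("rigid-body blade rotation matches the closed-form toy model", {
  # straight arm along +x: probe at radius 12, pivot at radius 5
  coords <- cbind(seq(12, 0, by = -1), 0, 0)
  sc <- rigid_body_scan(coords, pivot = 8, probe = 1, axis = "in_plane")
  expect_equal(sc$angle, seq(0, 180, by = 5))
  # law of cosines for the probe radius; neighbors sit 120 degrees apart so
  # the interblade distance is sqrt(3) times the probe radius
  c0 <- 5; L <- 7
  expected <- sqrt(3) * sqrt(c0^2 + L^2 + 2 * c0 * L * cos(sc$angle * pi / 180))
  expect_equal(sc$interblade_nm, expected, tolerance = 1e-6)
  # angle 0 reproduces the unrotated distance
  expect_equal(sc$interblade_nm[1], sqrt(3) * 12, tolerance = 1e-9)
  # out-of-plane 90 degrees: the probe's in-plane radius shrinks to the
  # pivot radius
  sco <- rigid_body_scan(coords, pivot = 8, probe = 1, axis = "out_of_plane")
  expect_equal(sco$interblade_nm[sco$angle == 90], sqrt(3) * 5,
               tolerance = 1e-6)
  # distances are continuous in the angle
  expect_lt(max(abs(diff(sc$interblade_nm))), 2)
})

test_that("blade rotation is rigid and fixes the pivot", {
  set.seed(81)
  coords <- cbind(cumsum(runif(20, 0.3, 0.8)) + 2, rnorm(20, 0, 0.4),
                  rnorm(20, 0, 0.2))
  sc <- rigid_body_scan(coords, pivot = 15, probe = 2,
                        angles = c(0, 35, 90, 140))
  at <- attr(sc, "coords_at")
  d0 <- dist(coords[1:14, ])
  for (a in c(35, 90, 140)) {
    rot <- at(a)
    expect_equal(as.numeric(dist(rot[1:14, ])), as.numeric(d0),
                 tolerance = 1e-6)
    expect_equal(rot[15, ], coords[15, ])       # pivot fixed exactly
    expect_equal(rot[16:20, ], coords[16:20, ]) # C-terminal side untouched
  }
  # unit declaration: angstrom inputs are converted to nm
  sc_ang <- rigid_body_scan(coords * 10, pivot = 15, probe = 2,
                            angles = 0, unit = "angstrom")
  expect_equal(sc_ang$interblade_nm[1], sc$interblade_nm[1], tolerance = 1e-9)
  # error paths
  expect_error(rigid_body_scan(coords, pivot = 99, probe = 1), "pivot")
  expect_error(rigid_body_scan(coords, pivot = 3, probe = 5), "N-terminal")
  expect_error(rigid_body_scan(coords[, 1:2], pivot = 3, probe = 1), "Nx3")
})
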