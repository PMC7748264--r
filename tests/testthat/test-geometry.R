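test_that("mesh area matches closed forms on planar point sets", {
  sq <- hemisphere(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
  expect_equal(sq$area, 10000)
  g <- as.matrix(expand.grid(x = seq(0, 20, 10), y = seq(0, 20, 10)))
  expect_equal(hemisphere(g)$area, 400)
  # area of a flat convex cloud equals its convex-hull (shoelace) area
  set.seed(3)
  pts <- cbind(runif(40, 0, 200), runif(40, 0, 200))
  h <- hemisphere(cbind(pts, 0))
  hp <- pts[grDevices::chull(pts), ]
  shoelace <- abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
                        c(hp[-1, 1], hp[1, 1]) * hp[, 2])) / 2
  expect_equal(h$area, shoelace, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected", {
  expect_error(hemisphere(cbind(c(0, 1), c(0, 1))), "at least 3")
  expect_error(hemisphere(cbind(0:5, 0:5, 0)), "collinear")
  expect_error(hemisphere(cbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 0))),
               "duplicate")
  expect_error(hemisphere(cbind(c(0, 1, NA), c(0, 0, 1), 0)), "finite")
})

test_that("spherical-cap mesh area approaches the closed-form cap area", {
  # quasi-regular sampling of a cap out to ~60 degrees half-angle
  area60 <- 2 * pi * 300^2 * (1 - cos(pi / 3))
  spacing <- sqrt(2 * area60 / (sqrt(3) * 200))
  h <- generate_hemisphere(200, "spherical-cap", spacing = spacing,
                           jitter = 2, cap_radius = 300, seed = 1)
  # closed-form area of the cap actually covered: the hull runs through the
  # boundary vertices, so use their mean geodesic radius
  bv <- unique(as.vector(h$boundary_edges))
  rho <- mean(acos(pmin(1, h$coords[bv, 3] / 300)) * 300)
  analytic <- 2 * pi * 300^2 * (1 - cos(rho / 300))
  expect_lt(abs(h$area / analytic - 1), 0.05)
})

test_that("geodesic distances follow the curved surface", {
  # pole to rim on a dense cap: geodesic ~ great-circle arc, chord is shorter
  R <- 300
  h <- generate_hemisphere(700, "spherical-cap", spacing = 25, jitter = 1,
                           cap_radius = R, seed = 2)
  d <- distance_matrix(h, "geodesic")
  de <- distance_matrix(h, "euclidean")
  rho <- acos(pmin(1, h$coords[, 3] / R)) * R
  pole <- which.min(rho)
  rim <- which.max(rho)
  arc <- abs(rho[rim] - rho[pole])
  expect_gt(d$entries[pole, rim], de$entries[pole, rim])
  # edge paths follow lattice directions: at least the great-circle arc
  # (minus sub-percent chordal shortening), at most the triangular-lattice
  # detour bound of 2/sqrt(3)
  ratio <- d$entries[pole, rim] / arc
  expect_gt(ratio, 0.97)
  expect_lt(ratio, 2 / sqrt(3) + 0.01)
  expect_true(all(d$entries >= de$entries - 1e-9))
})

test_that("distance matrices are symmetric, zero-diagonal and metric", {
  h <- grid_hemisphere(5, 5, 10, jitter = 2)
  for (metric in c("geodesic", "euclidean")) {
    d <- distance_matrix(h, metric)$entries
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d[upper.tri(d)] > 0))
    set.seed(1)
    for (k in 1:50) {
      ijk <- sample(nrow(d), 3)
      expect_lte(d[ijk[1], ijk[2]],
                 d[ijk[1], ijk[3]] + d[ijk[3], ijk[2]] + 1e-9)
    }
  }
  # adjacent cells on a flat grid: geodesic equals the straight line
  g <- grid_hemisphere(3, 3, 10)
  expect_equal(distance_matrix(g, "geodesic")$entries[1, 2], 10,
               tolerance = 1e-12)
})

test_that("disconnected meshes are reported", {
  h <- grid_hemisphere(4, 4, 10)
  h$flat <- FALSE # force the graph route
  keep <- h$edges[h$edges[, 1] <= 8 & h$edges[, 2] <= 8 |
                    h$edges[, 1] > 8 & h$edges[, 2] > 8, ]
  h$edges <- keep
  expect_error(distance_matrix(h, "geodesic"), "disconnected")
})

test_that("edge correction weights reflect the disc fraction inside", {
  g <- as.matrix(expand.grid(x = seq(0, 400, 10), y = seq(0, 400, 10)))
  h <- hemisphere(g)
  ctr <- which(g[, 1] == 200 & g[, 2] == 200)
  edge <- which(g[, 1] == 0 & g[, 2] == 200)
  corner <- which(g[, 1] == 0 & g[, 2] == 0)
  expect_equal(edge_correction(h, ctr, 30), 1)
  expect_equal(edge_correction(h, edge, 30), 0.5, tolerance = 0.05)
  expect_equal(edge_correction(h, corner, 30), 0.25, tolerance = 0.05)
  # non-increasing in r for a boundary cell
  w <- edge_weights(h, edge, c(20, 50, 100, 150))
  expect_true(all(diff(drop(w)) <= 1e-9))
  expect_true(all(w > 0 & w <= 1))
  expect_error(edge_correction(h, ctr, -5), "positive")
  expect_error(edge_correction(h, 10^6, 5), "invalid")
})

test_that("curved-mesh edge correction detects the cap rim", {
  h <- generate_hemisphere(250, "spherical-cap", spacing = 25, jitter = 1,
                           cap_radius = 300, seed = 4)
  rho <- acos(pmin(1, h$coords[, 3] / 300)) * 300
  pole <- which.min(rho)
  rim <- which.max(rho)
  expect_equal(edge_correction(h, pole, 40), 1, tolerance = 0.02)
  w_rim <- edge_correction(h, rim, 40)
  expect_lt(w_rim, 0.8)
  expect_gt(w_rim, 0.2)
})
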