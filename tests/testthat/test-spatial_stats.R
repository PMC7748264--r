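test_that("spatial K matches hand enumeration on the 3x3 grid", {
  g <- as.matrix(expand.grid(x = seq(0, 20, 10), y = seq(0, 20, 10)))
  h <- hemisphere(g) # A = 400
  d <- distance_matrix(h, "geodesic")
  i00 <- which(g[, 1] == 0 & g[, 2] == 0)
  i10 <- which(g[, 1] == 10 & g[, 2] == 0)
  i22 <- which(g[, 1] == 20 & g[, 2] == 20)
  p <- labeled_pattern(h, s1 = c(i00, i10))
  expect_equal(ripley_spatial(p, d, c(5, 15), edge_correction = "none"),
               c(0, 200))
  pst <- labeled_pattern(h, s1 = i00, s2 = c(i10, i22))
  expect_equal(ripley_spatiotemporal(pst, d, 15, edge_correction = "none"),
               200)
})

test_that("single-event and empty patterns behave as specified", {
  h <- grid_hemisphere(4, 4, 10)
  d <- distance_matrix(h, "geodesic")
  p1 <- labeled_pattern(h, s1 = 5L)
  expect_equal(ripley_spatial(p1, d, c(10, 50)), c(0, 0))
  expect_error(ripley_spatial(labeled_pattern(h, integer()), d, 10),
               "no events")
  expect_error(
    ripley_spatiotemporal(labeled_pattern(h, 1L, integer()), d, 10),
    "no events")
})

test_that("brute-force double loop reproduces both K statistics exactly", {
  set.seed(42)
  for (rep in 1:12) {
    n_side <- sample(4:5, 1)
    h <- grid_hemisphere(n_side, n_side, 12, jitter = 3, seed = rep)
    n <- n_cells(h)
    d <- distance_matrix(h, "geodesic")
    radii <- c(10, 25, 40, 80)
    s <- sample(n, sample(3:8, 1))
    p <- labeled_pattern(h, s1 = s)
    for (ec in c("none", "fraction")) {
      w <- if (ec == "none") NULL else edge_weights(h, s, radii)
      expect_equal(ripley_spatial(p, d, radii, edge_correction = ec),
                   k_spatial_bruteforce(h, s, d$entries, radii, w),
                   tolerance = 1e-12)
    }
    s1 <- sample(n, sample(2:6, 1))
    s2 <- sample(n, sample(2:6, 1)) # may overlap s1 on purpose
    pst <- labeled_pattern(h, s1 = s1, s2 = s2)
    w1 <- edge_weights(h, s1, radii)
    expect_equal(
      ripley_spatiotemporal(pst, d, radii, edge_correction = "fraction"),
      k_st_bruteforce(h, s1, s2, d$entries, radii, w1),
      tolerance = 1e-12)
  }
})

test_that("sampling envelope is deterministic and degenerates when S = N", {
  h <- grid_hemisphere(5, 5, 10, jitter = 2)
  d <- distance_matrix(h, "geodesic")
  p <- labeled_pattern(h, s1 = sample(25, 6))
  radii <- seq(10, 60, 10)
  e1 <- sampling_envelope(p, d, radii, "spatial", seed = 9)
  e2 <- sampling_envelope(p, d, radii, "spatial", seed = 9)
  expect_identical(e1, e2)
  pall <- labeled_pattern(h, s1 = 1:25)
  eall <- sampling_envelope(pall, d, radii, "spatial", seed = 1)
  kobs <- ripley_spatial(pall, d, radii)
  expect_equal(eall$q05, kobs)
  expect_equal(eall$q95, kobs)
})

test_that("a random event set falls inside the envelope about 90% of the time", {
  h <- grid_hemisphere(8, 8, 13, jitter = 3)
  d <- distance_matrix(h, "geodesic")
  n <- n_cells(h)
  radius <- 40
  set.seed(5)
  inside <- vapply(1:120, function(b) {
    s <- sample(n, 10)
    p <- labeled_pattern(h, s1 = s)
    k <- ripley_spatial(p, d, radius, edge_correction = "none")
    e <- sampling_envelope(p, d, radius, "spatial",
                           edge_correction = "none")
    k >= e$q05 && k <= e$q95
  }, TRUE)
  expect_gt(mean(inside), 0.78)
  expect_lt(mean(inside), 0.98)
})

test_that("standardization maps the envelope to +/-1 and classifies", {
  expect_equal(standardize_k(c(5, 1, 3), c(1, 1, 1), c(5, 5, 5)),
               c(1, -1, 0))
  expect_equal(standardize_k(4, 4, 4), 0) # degenerate envelope
  expect_error(standardize_k(1:3, 1:2, 1:2), "length")
  radii <- seq(10, 200, 10)
  expect_equal(as.character(classify_pattern(rep(1.2, 20), radii)),
               "aggregated")
  expect_equal(as.character(classify_pattern(rep(0, 20), radii)), "random")
  expect_equal(as.character(classify_pattern(rep(-1.5, 20), radii)),
               "dispersed")
  # only radii inside the 30-150 window count
  z <- c(rep(100, 2), rep(0, 13), rep(100, 5))
  expect_equal(as.character(classify_pattern(z, radii)), "random")
  expect_error(classify_pattern(c(1, 2), c(200, 300)), "window")
})

test_that("strongly aggregated Time-2 events exceed the envelope", {
  h <- generate_hemisphere(900, seed = 3)
  d <- distance_matrix(h, "geodesic")
  ent <- d$entries
  s1 <- sample(n_cells(h), 6)
  near <- which(apply(ent[s1, ], 2, min) <= 40)
  s2 <- setdiff(near, s1)[1:15]
  p <- labeled_pattern(h, s1 = s1, s2 = s2)
  k <- ripley_spatiotemporal(p, d, 40)
  e <- sampling_envelope(p, d, 40, "spatiotemporal", seed = 2)
  expect_gt(k, e$q95)
  rc <- ripley_curve(p, d, seq(10, 150, 10), "spatiotemporal", seed = 2)
  expect_equal(rc$classification, "aggregated")
})
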