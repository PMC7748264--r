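test_that("placement log-likelihood matches the worked example", {
  set.seed(1)
  coords <- cbind(runif(10, 0, 500), runif(10, 0, 500), 0)
  h <- hemisphere(coords)
  d <- distance_matrix(h, "euclidean")
  dm <- d$entries[1, ]
  ord <- order(dm)
  r <- (dm[ord[4]] + dm[ord[5]]) / 2 # exactly 3 candidates inside r
  inside <- ord[2]
  expect_equal(interaction_loglik(h, 1, inside, interaction_params(2, r), d),
               log(2 / 12))
  expect_equal(interaction_loglik(h, 1, inside, interaction_params(1, r), d),
               log(1 / 9))
  # g -> Inf concentrates all mass on the 3 inside candidates
  expect_equal(
    interaction_loglik(h, 1, inside, interaction_params(1e12, r), d),
    log(1 / 3), tolerance = 1e-9)
})

test_that("enumeration oracle agrees on random small configurations", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(8:12, 1)
    coords <- cbind(runif(n, 0, 300), runif(n, 0, 300), 0)
    h <- hemisphere(coords)
    d <- distance_matrix(h, "euclidean")
    s1 <- sample(n, sample(1:3, 1))
    s2 <- sample(setdiff(seq_len(n), s1), sample(1:4, 1))
    g <- runif(1, 0.2, 4)
    r <- runif(1, 20, 250)
    expect_equal(
      interaction_loglik(h, s1, s2, interaction_params(g, r), d),
      loglik_enumeration(n, s1, s2, g, r, d$entries),
      tolerance = 1e-12)
  }
})

test_that("at g = 1 the likelihood is flat in r", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 30
    h <- hemisphere(cbind(runif(n, 0, 400), runif(n, 0, 400), 0))
    d <- distance_matrix(h, "euclidean")
    s1 <- sample(n, 3)
    s2 <- sample(setdiff(1:n, s1), 5)
    ll <- vapply(c(15, 60, 120, 290), function(r)
      interaction_loglik(h, s1, s2, interaction_params(1, r), d), 0)
    expect_equal(max(ll) - min(ll), 0)
    expect_equal(ll[1], -5 * log(n - 3))
  }
})

test_that("likelihood rises with g when all Time-2 events lie inside", {
  set.seed(2)
  n <- 25
  h <- hemisphere(cbind(runif(n, 0, 300), runif(n, 0, 300), 0))
  d <- distance_matrix(h, "euclidean")
  s1 <- 1L
  inside <- order(d$entries[1, ])[2:4]
  ll <- vapply(c(0.5, 1, 2, 4, 8), function(g)
    interaction_loglik(h, s1, inside, interaction_params(g, 150), d), 0)
  expect_true(all(diff(ll) > 0))
})

test_that("Time-2 events also present in S1 are dropped as DLS", {
  h <- grid_hemisphere(4, 4, 10)
  d <- distance_matrix(h, "euclidean")
  expect_warning(
    ll <- interaction_loglik(h, c(1, 2), c(2, 5),
                             interaction_params(1, 20), d),
    "Time 1")
  expect_equal(ll, -log(14)) # one remaining event, uniform over 14
})

test_that("the combined fit reduces to the single-dataset likelihood", {
  set.seed(4)
  n <- 40
  h <- hemisphere(cbind(runif(n, 0, 500), runif(n, 0, 500), 0))
  d <- distance_matrix(h, "euclidean")
  s1 <- sample(n, 4)
  s2 <- sample(setdiff(1:n, s1), 6)
  fit <- fit_interaction(list(list(s1 = s1, s2 = s2, d = d)),
                         n_samples = 1500, seed = 5)
  expect_equal(fit$loglik,
               unname(interaction_loglik(
                 h, s1, s2,
                 interaction_params(unname(fit$ml["g"]),
                                    unname(fit$ml["r"])), d)),
               tolerance = 1e-9)
  expect_true(fit$ml["g"] >= 0.1 && fit$ml["g"] <= 5)
  expect_true(fit$ml["r"] >= 10 && fit$ml["r"] <= 300)
  expect_equal(dim(fit$samples), c(1500L, 2L))
  expect_true(all(fit$samples[, "g"] >= 0.1 & fit$samples[, "g"] <= 5))
})

test_that("constant-model strength test behaves at the boundaries", {
  s <- strength_significance(rep(1, 5))
  expect_equal(s$estimate, 0)
  expect_equal(s$p_value, 1)
  s2 <- strength_significance(c(1.2, 1.2, 1.2, 1.2) +
                                c(1e-4, -1e-4, 2e-4, -2e-4))
  expect_equal(s2$estimate, 0.2, tolerance = 1e-3)
  expect_lt(s2$p_value, 1e-6)
  expect_error(strength_significance(1.1), "at least two")
})

test_that("strength test holds its nominal type-I error", {
  set.seed(8)
  rej <- vapply(1:1000, function(b) {
    s <- 1 + rnorm(8, 0, 0.1)
    strength_significance(s)$p_value < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.025)
  expect_lt(mean(rej), 0.085)
})
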