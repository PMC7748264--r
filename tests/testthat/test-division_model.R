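test_that("lag-exponential density and draws respect delay and scale", {
  expect_equal(dlagexp(16.5, beta = 1.6, d = 16.6), 0)
  expect_equal(dlagexp(16.6, beta = 1.6, d = 16.6), 1 / 1.6)
  x <- seq(0, 200, 0.01)
  expect_equal(sum(dlagexp(x, 85.3, 22.2)) * 0.01,
               1 - exp(-(200 - 22.2) / 85.3), tolerance = 1e-3)
  set.seed(1)
  draws <- rlagexp(5000, beta = 85.3, d = 22.2)
  expect_true(all(draws >= 22.2))
  expect_equal(mean(draws), 107.5, tolerance = 5) # d + beta
  expect_error(rlagexp(10, beta = -1, d = 5), "positive")
})

test_that("parameter containers validate their invariants", {
  expect_error(cell_cycle_params(22, 85, 17, 1.6, 1.5), "p_rediv")
  expect_error(cell_cycle_params(-1, 85, 17, 1.6, 0.4), "positive")
  expect_error(cell_cycle_params(10, 5, 12, 8, 0.4), "shorter")
  k <- fitted_kinetics()
  expect_equal(k$d_cc + k$beta_cc, 107.5)
  expect_equal(k$d_sp + k$beta_sp, 18.2)
})

test_that("cohort histories respect the kinetic constraints", {
  kin <- fitted_kinetics()
  coh <- simulate_cohort(kin, 4000, 450, seed = 3)
  expect_true(all(coh$s_end - coh$s_start >= kin$d_sp))
  expect_true(all(coh$division - coh$birth >= kin$d_cc))
  expect_true(all(coh$s_end - coh$s_start <= coh$division - coh$birth))
  expect_true(all(coh$s_start >= coh$birth))
  # no chains without redivision
  k0 <- cell_cycle_params(22.2, 85.3, 16.6, 1.6, 0)
  coh0 <- simulate_cohort(k0, 2000, 450, seed = 4)
  expect_true(all(coh0$generation == 1L))
  # redividing daughters appear at the expected rate (one-daughter variant)
  coh1 <- simulate_cohort(kin, 20000, 450, seed = 5, per_daughter = FALSE)
  n_div <- sum(coh1$division <= 450)
  n_rediv <- sum(coh1$redivider)
  se <- sqrt(0.38 * 0.62 / n_div)
  expect_lt(abs(n_rediv / n_div - 0.38), 3 * se + 0.01)
  # per-daughter variant doubles the redividing offspring
  coh2 <- simulate_cohort(kin, 20000, 450, seed = 5, per_daughter = TRUE)
  expect_gt(sum(coh2$redivider), 1.6 * n_rediv)
})

test_that("virtual double labeling classifies hand-built histories", {
  hist <- data.frame(cell_id = 1:3, parent_id = c(NA, 1L, NA),
                     birth = c(0, 30, 0), division = c(30, 110, 200),
                     s_start = c(10, 80, 150), s_end = c(28, 98, 170),
                     redivider = c(FALSE, TRUE, FALSE),
                     generation = c(1L, 2L, 1L))
  attr(hist, "t_end") <- 250
  # DLS: one S-phase covering both snapshots
  rd <- virtual_double_label(hist, 20, 26)
  expect_equal(rd$n_labeled_t1, 1L)
  expect_equal(rd$n_dls, 1L)
  expect_equal(rd$n_rediv, 0L)
  # redivision: daughter S-phase covers t2
  rd2 <- virtual_double_label(hist, 20, 92)
  expect_equal(rd2$n_labeled_t1, 1L)
  expect_equal(rd2$n_dls, 0L)
  expect_equal(rd2$n_rediv, 1L)
  expect_equal(rd2$rediv_fraction, 1)
  expect_error(virtual_double_label(hist, 20, 300), "beyond")
  expect_error(virtual_double_label(hist, 30, 20), "before")
})

test_that("DLS decays with the labeling interval and vanishes by 32 h", {
  kin <- fitted_kinetics()
  coh <- simulate_cohort(kin, 30000, 450, seed = 6)
  dls <- vapply(c(9, 18, 24, 32, 48, 72), function(dt)
    virtual_double_label(coh, 450 - dt, 450)$dls_fraction, 0)
  expect_true(all(diff(dls) <= 1e-9))
  expect_true(all(dls[4:6] == 0)) # P(S > 32 h) ~ e^(-(32-16.6)/1.6) ~ 1e-5
  rediv <- vapply(c(9, 48), function(dt)
    virtual_double_label(coh, 450 - dt, 450)$rediv_fraction, 0)
  expect_lt(rediv[1], 0.02) # essentially none at 9 h
  expect_gt(rediv[2], 0.05) # plateau at long intervals
  # snapshot observation can only miss redivisions
  expect_lt(rediv[2], kin$p_rediv)
})

test_that("continuous labeling recovers the redivision probability", {
  # with whole-interval observation every re-entry of a divided mother is
  # seen, so the observed frequency approaches p_rediv (one-daughter case)
  kin <- fitted_kinetics()
  coh <- simulate_cohort(kin, 15000, 450, seed = 8, per_daughter = FALSE)
  mothers <- coh[coh$division <= 250, ]
  kids <- coh[!is.na(coh$parent_id), ]
  observed <- mean(mothers$cell_id %in% kids$parent_id)
  se <- sqrt(0.38 * 0.62 / nrow(mothers))
  expect_lt(abs(observed - kin$p_rediv), 3 * se + 0.01)
})

test_that("the ABC summary distance is a proper pseudo-metric on tables", {
  obs <- data.frame(delta_t = rep(c(9, 18, 24), each = 3),
                    rediv = runif(9), dls = runif(9))
  expect_equal(abc_distance(obs, obs), 0)
  o <- data.frame(delta_t = 9, rediv = c(0.1, 0.1), dls = c(0, 0))
  s <- data.frame(delta_t = 9, rediv = c(0.2, 0.2), dls = c(0, 0))
  expect_equal(abc_distance(o, s), 0.1)
  set.seed(2)
  sim <- transform(obs, rediv = runif(9), dls = runif(9))
  expect_equal(abc_distance(obs, sim), abc_distance(sim, obs))
  expect_gte(abc_distance(obs, sim), 0)
  expect_error(abc_distance(obs, sim[sim$delta_t != 24, ]), "match")
})

test_that("fraction tables from known kinetics feed the ABC machinery", {
  k0 <- cell_cycle_params(22.2, 85.3, 16.6, 1.6, 0)
  tab <- generate_observed_fractions(k0, hemispheres_per_interval = 2,
                                     intervals = c(9, 24, 48),
                                     n_cells = 3000, seed = 9)
  expect_true(all(tab$rediv[is.finite(tab$rediv)] == 0))
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$dls[tab$delta_t == 48] == 0))
})
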