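kin <- fitted_kinetics()

test_that("without division events the population stays constant", {
  cfg <- sim_config(p_div = 0, p_rediv = 0, n_target = 600, n_init = 50,
                    t_stop = 200, seed = 1)
  traj <- simulate_population(cfg, kin)
  expect_equal(sum(traj$cells$alive), 50L)
  expect_equal(nrow(traj$divisions), 0L)
  expect_equal(traj$t_end, 200)
})

test_that("a growing colony respects the configured rates", {
  cfg <- sim_config(n_init = 300, n_target = 800, seed = 2)
  traj <- simulate_population(cfg, kin)
  cells <- traj$cells
  expect_equal(sum(cells$alive & cells$gfap), 800L)
  dv <- traj$divisions
  # per-daughter re-entry: redividing daughters / daughters ~ p_rediv
  se <- sqrt(0.38 * 0.62 / (2 * nrow(dv)))
  expect_lt(abs(sum(dv$redivider) / (2 * nrow(dv)) - 0.38), 3 * se)
  # one-daughter variant: divisions flagged ~ Bernoulli(p_rediv)
  tr1 <- simulate_population(
    sim_config(n_init = 300, n_target = 700, per_daughter_rediv = FALSE),
    kin, seed = 3)
  dv1 <- tr1$divisions
  se1 <- sqrt(0.38 * 0.62 / nrow(dv1))
  expect_lt(abs(mean(dv1$redivider) - 0.38), 3 * se1 + 0.01)
  # ~10% gfap-negative daughters
  se10 <- sqrt(0.1 * 0.9 / nrow(dv))
  expect_lt(abs(mean(dv$gfapneg) - 0.10), 3 * se10 + 0.01)
  # bookkeeping: alive = init + divisions - removals
  expect_equal(sum(cells$alive),
               cfg$n_init + nrow(dv) - sum(!cells$alive))
  # cell positions stay distinct
  pos <- cells[cells$alive, c("x", "y")]
  expect_gt(min(dist(pos)), 0.5)
})

test_that("identical seeds reproduce the trajectory and measurement", {
  cfg <- sim_config(n_init = 200, n_target = 420)
  t1 <- simulate_population(cfg, kin, seed = 33)
  t2 <- simulate_population(cfg, kin, seed = 33)
  expect_identical(t1$cells, t2$cells)
  p1 <- virtual_measurement(t1, 24, seed = 5)
  p2 <- virtual_measurement(t2, 24, seed = 5)
  expect_identical(p1$s1, p2$s1)
  expect_identical(p1$s2, p2$s2)
})

test_that("virtual measurements label S-phases consistently", {
  cfg <- sim_config(n_init = 300, n_target = 900, seed = 7)
  traj <- simulate_population(cfg, kin)
  p <- virtual_measurement(traj, 48, seed = 1)
  n <- n_cells(p$hemisphere)
  expect_true(all(p$s1 >= 1 & p$s1 <= n))
  expect_true(all(p$dls %in% p$s1))
  # snapshot S-phase fraction near p_div x mean S-phase length
  expect_gt(length(p$s1) / n, 0.005)
  expect_lt(length(p$s1) / n, 0.04)
  # delta_t = 0: the two snapshots coincide and every label is a DLS
  p0 <- virtual_measurement(traj, 0, seed = 1)
  expect_identical(sort(p0$s1), sort(p0$s2))
  expect_identical(sort(p0$dls), sort(p0$s1))
})

test_that("redivision couples successive S-phases in space", {
  # the mechanistic source of aggregation: redividing daughters sit next to
  # their Time-1-labeled mothers, so s1-s2 distances shrink vs control
  mindists <- function(p) {
    ent <- distance_matrix(p$hemisphere, "euclidean")$entries
    s2 <- setdiff(p$s2, p$s1)
    apply(ent[p$s1, s2, drop = FALSE], 2, min)
  }
  pool_r <- c(); pool_c <- c()
  for (s in 1:3) {
    tr <- simulate_population(sim_config(n_init = 400, n_target = 1200),
                              kin, seed = 40 + s)
    pool_r <- c(pool_r, mindists(virtual_measurement(tr, 48, seed = s)))
    tc <- simulate_population(control_config(n_init = 400, n_target = 1200),
                              kin, seed = 80 + s)
    pool_c <- c(pool_c, mindists(virtual_measurement(tc, 48, seed = s)))
  }
  expect_lt(min(pool_r), min(pool_c))
  expect_lt(mean(pool_r < 20), 0.5) # coupling is a minority of events
  expect_gt(mean(pool_r < 20), mean(pool_c < 20))
})

test_that("agent and cohort models agree on labeling observables", {
  # same kinetics, same one-daughter redivision rule: the spatial model's
  # readouts must be statistically consistent with the nonspatial model
  dt <- 48
  n1 <- 0L; nrd <- 0L
  for (s in 1:3) {
    tr <- simulate_population(sim_config(n_init = 400, n_target = 1100),
                              kin, seed = 140 + s)
    p <- virtual_measurement(tr, dt, seed = s)
    n1 <- n1 + length(p$s1)
    nrd <- nrd + attr(p, "n_rediv")
  }
  agent_frac <- nrd / n1
  coh <- simulate_cohort(kin, 40000, 450, seed = 9, per_daughter = TRUE)
  cohort_frac <- virtual_double_label(coh, 450 - dt, 450)$rediv_fraction
  se <- sqrt(cohort_frac * (1 - cohort_frac) / n1)
  expect_lt(abs(agent_frac - cohort_frac), 4 * se + 0.02)
})
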