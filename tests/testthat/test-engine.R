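# Engine: configuration validation, initialisation, determinism, restart,
# schedules, constraints, and conservation in the reduced mode.

test_that("hematocrit sets the channel length; placed cells realise it", {
  cfg <- simulation_config(n_cells = 8, hct = 0.02, n_macs = 1,
                           condition = "sickle_hypoxia", seed = 4)
  expect_equal(8 * cfg$a_cell / (cfg$L * cfg$h), 0.02, tolerance = 1e-12)
  st <- initialize_state(cfg)
  a_tot <- sum(vapply(seq_len(8), function(c) {
    idx <- ((c - 1) * 40 + 1):(c * 40)
    abs(splenosim:::polygon_area(st$kstate$pos[idx, ]))
  }, numeric(1)))
  expect_lt(abs(a_tot / (0.02 * cfg$L * cfg$h) - 1), 0.05)
})

test_that("hematocrit variation is realised by changing channel length", {
  Ls <- vapply(c(0.015, 0.028, 0.036, 0.05), function(hc)
    simulation_config(n_cells = 10, hct = hc, n_macs = 1)$L, numeric(1))
  expect_equal(Ls[1] / Ls[4], 0.05 / 0.015, tolerance = 1e-12)
  expect_true(all(diff(Ls) < 0))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_cells = 4, hct = 0.9), "hematocrit")
  expect_error(simulation_config(n_cells = 4, hct = 0.02,
                                 velocity = data.frame(time = 0, v = -5)))
})

test_that("infeasible packings report the achievable hematocrit", {
  expect_error(
    initialize_state(simulation_config(n_cells = 30, hct = NULL, L = 40,
                                       n_macs = 1, seed = 1)),
    "achievable hematocrit")
})

test_that("a zero-cell configuration is a valid pure-fluid run", {
  cfg <- simulation_config(n_cells = 0, hct = NULL, L = 50, n_macs = 1)
  st <- initialize_state(cfg)
  out <- run_sim(st, 0.01, record_dt = 0)
  expect_equal(out$state$kstate$time, 0.01, tolerance = 1e-9)
})

test_that("identical config and seed give bitwise-identical trajectories", {
  cfg <- simulation_config(n_cells = 3, hct = 0.02, n_macs = 1,
                           condition = "sickle_hypoxia", seed = 9)
  r1 <- run_sim(initialize_state(cfg), 0.3, record_dt = 0.01)
  r2 <- run_sim(initialize_state(cfg), 0.3, record_dt = 0.01)
  expect_identical(r1$state$kstate$pos, r2$state$kstate$pos)
  expect_identical(r1$state$kstate$vel, r2$state$kstate$vel)
  expect_identical(r1$trajectory$nb, r2$trajectory$nb)
})

test_that("save/load restart continues bitwise-identically", {
  cfg <- simulation_config(n_cells = 3, hct = 0.02, n_macs = 1,
                           condition = "sickle_hypoxia", seed = 5)
  full <- run_sim(initialize_state(cfg), 0.4, record_dt = 0)
  half <- run_sim(initialize_state(cfg), 0.2, record_dt = 0)
  f <- tempfile(fileext = ".rds")
  save_state(half$state, f)
  resumed <- run_sim(load_state(f), 0.2, record_dt = 0)
  expect_identical(full$state$kstate$pos, resumed$state$kstate$pos)
  expect_identical(full$state$kstate$bond_on, resumed$state$kstate$bond_on)
})

test_that("time_scaling relabels reported times without touching dynamics", {
  cfg1 <- simulation_config(n_cells = 2, hct = 0.02, n_macs = 1, seed = 3,
                            time_scaling = 1)
  cfg2 <- simulation_config(n_cells = 2, hct = 0.02, n_macs = 1, seed = 3,
                            time_scaling = 7)
  r1 <- run_sim(initialize_state(cfg1), 0.2, record_dt = 0.01)
  r2 <- run_sim(initialize_state(cfg2), 0.2, record_dt = 0.01)
  expect_identical(r1$state$kstate$pos, r2$state$kstate$pos)
  expect_equal(r2$trajectory$t, 7 * r1$trajectory$t)
})

test_that("membrane area drifts less than 1% over 1e5 steps", {
  cfg <- simulation_config(n_cells = 1, hct = NULL, L = 60, n_macs = 1,
                           condition = "sickle_hypoxia", velocity = 150,
                           seed = 2)
  st <- initialize_state(cfg)
  out <- run_sim(st, 10, record_dt = 0)  # 1e5 steps at dt = 1e-4
  expect_lt(abs(out$area / cfg$a_cell - 1), 0.01)
})

test_that("without binding, cells advect past the macrophages", {
  off <- adhesion_params(Ks = 1, kon0 = 0, koff0 = 1, check_ranges = FALSE)
  cfg <- simulation_config(n_cells = 1, hct = NULL, L = 80,
                           condition = "sickle_hypoxia", adhesion = off,
                           macrophages = data.frame(x = 40, radius = 9),
                           velocity = 150, seed = 1,
                           placement = data.frame(x = 10, z = 9, angle = 0),
                           aggregation = aggregation_params(enabled = FALSE))
  st <- initialize_state(cfg)
  r <- run_sim(st, 3, record_dt = 0.02)
  expect_identical(max(r$trajectory$nb), 0L)
  expect_gt(max(r$trajectory$comx[, 1]), 60)  # carried well past the cap
})

test_that("step-wise velocity schedules drive the flow as programmed", {
  sched <- data.frame(time = c(0, 1), v = c(300, 50))
  cfg <- simulation_config(n_cells = 1, hct = NULL, L = 60, n_macs = 0,
                           condition = "sickle_hypoxia", velocity = sched,
                           seed = 1,
                           placement = data.frame(x = 5, z = 10, angle = 0),
                           aggregation = aggregation_params(enabled = FALSE))
  st <- initialize_state(cfg)
  r <- run_sim(st, 2.8, record_dt = 0.01)
  tr <- r$trajectory
  u1 <- mean(tr$speed[tr$t_sim > 0.7 & tr$t_sim < 1, 1])
  u2 <- mean(tr$speed[tr$t_sim > 2.5, 1])
  expect_gt(u1, 100)
  expect_lt(u2, 60)
})
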