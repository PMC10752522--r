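# DPD solvent: fluctuation-dissipation enforcement, pairwise force laws,
# thermostat accuracy, momentum conservation, and the reduced-mode coupling.

test_that("inconsistent random-force amplitude is rejected", {
  expect_error(dpd_params(gamma = 4.5, kBT = 1, sigma = 2),
               "fluctuation-dissipation")
  p <- dpd_params(gamma = 4.5, kBT = 1)
  expect_equal(p$sigma^2, 2 * 4.5)
})

test_that("pair forces are antisymmetric, cut off, and finite at contact", {
  p <- dpd_params()
  set.seed(1)
  pos <- matrix(runif(40, 0, 3), ncol = 2)
  vel <- matrix(rnorm(40), ncol = 2)
  f <- dpd_pair_forces(pos, vel, p, seed = 9)
  expect_lt(max(abs(colSums(f))), 1e-10)      # Newton's third law, exactly
  pos2 <- matrix(c(0, 0, 1.2, 0), 2, byrow = TRUE)
  f2 <- dpd_pair_forces(pos2, matrix(0, 2, 2), p, seed = 1)
  expect_identical(max(abs(f2)), 0)           # beyond r_c: no interaction
  pos3 <- matrix(0, 2, 2)                     # exact overlap: soft, finite
  f3 <- dpd_pair_forces(pos3, matrix(0, 2, 2), p, seed = 1)
  expect_true(all(is.finite(f3)))
})

test_that("the equilibrium kinetic temperature matches kBT within 3%", {
  p <- dpd_params()
  temps <- vapply(1:3, function(s)
    dpd_equilibrium(p, Lx = 8, Lz = 8, n_steps = 3000, warmup = 800,
                    seed = s)$temperature, numeric(1))
  expect_lt(abs(mean(temps) - 1), 0.03)
})

test_that("pair forces conserve total momentum exactly during a run", {
  p <- dpd_params()
  eq <- dpd_equilibrium(p, Lx = 8, Lz = 8, n_steps = 1500, warmup = 500,
                        seed = 2)
  expect_lt(eq$max_pair_force_sum, 1e-9)
  expect_lt(max(abs(eq$momentum)), 1e-9)
})

test_that("reduced-mode coupling forces drag vertices toward the flow", {
  con <- model_constants()
  dom <- channel_domain(L = 60, h = 20, U_top = 300)
  pos <- cbind(c(10, 20), c(5, 15))
  vel <- matrix(0, 2, 2)
  out <- couple_membrane(pos, vel, dom, con)
  expect_equal(out$membrane[, 1],
               con$zeta_v * couette_profile(pos[, 2], 300, 20))
  expect_equal(out$fluid_reaction, -colSums(out$membrane))
  expect_error(couple_membrane(cbind(10, 25), matrix(0, 1, 2), dom, con),
               "outside")
})

test_that("a freely suspended cell advects with the local flow", {
  cfg <- simulation_config(n_cells = 1, hct = NULL, L = 60, n_macs = 0,
                           condition = "sickle_hypoxia", velocity = 150,
                           placement = data.frame(x = 10, z = 10, angle = 0),
                           aggregation = aggregation_params(enabled = FALSE))
  st <- initialize_state(cfg)
  run <- run_sim(st, 2, record_dt = 0.01)  # placed cells start at rest
  tr <- run$trajectory
  n <- length(tr$t)
  tail_i <- (3 * n %/% 4):n
  u_exp <- couette_profile(mean(tr$comz[tail_i, 1]), 150, 20)
  u_obs <- mean(tr$speed[tail_i, 1])
  expect_lt(abs(u_obs / u_exp - 1), 0.15)
})
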