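# Stochastic bond kinetics: closed-form rate/probability checks, calibrated
# presets, Monte-Carlo update rules, bond mechanics, Morse aggregation.

test_that("formation and dissociation rates follow the Gaussian-well form", {
  p <- adhesion_params(Ks = 2.9, kon0 = 5.42e4, koff0 = 2.71)
  expect_equal(formation_rate(p$l0, p), p$kon0)
  expect_equal(dissociation_rate(p$l0, p), p$koff0)
  # even in (l - l0)
  expect_equal(formation_rate(p$l0 + 0.2, p), formation_rate(p$l0 - 0.2, p))
  # sigma = 0 makes the rate constant
  p0 <- adhesion_params(Ks = 2.9, sigma_on = 0.5, sigma_off = 0.05,
                        kon0 = 1e4, koff0 = 1)
  p0$sigma_on <- 0; p0$sigma_off <- 0
  expect_equal(formation_rate(c(0, 0.3, 0.7), p0), rep(1e4, 3))
  expect_equal(dissociation_rate(c(0, 0.3, 0.7), p0), rep(1, 3))
  # characteristic displacements, against direct scalar evaluation of the
  # rate law: sqrt(kBT/sigma) gives e^{-1/2}, sqrt(2 kBT/sigma) gives e^{-1}
  expect_equal(formation_rate(p$l0 + sqrt(p$kBT / p$sigma_on), p),
               p$kon0 * exp(-0.5), tolerance = 1e-12)
  expect_equal(formation_rate(p$l0 + sqrt(2 * p$kBT / p$sigma_on), p),
               p$kon0 * exp(-1), tolerance = 1e-12)
})

test_that("per-step probabilities are exact and bounded", {
  expect_equal(formation_probability(log(2) / 1e-3, 1e-3), 0.5)
  expect_lt(formation_probability(1e4, 1e-9), 1e-4)
  k <- 10^seq(-2, 5, length.out = 30)
  pr <- formation_probability(k, 1e-4)
  expect_true(all(pr >= 0 & pr < 1))
  expect_true(all(diff(pr) > 0))
})

test_that("the oxygenation presets carry the calibrated parameter values", {
  no <- adhesion_preset("normoxia")
  hy <- adhesion_preset("hypoxia")
  expect_identical(c(no$kon0, no$koff0, no$Ks), c(5.42e4, 2.71, 2.9))
  expect_identical(c(hy$kon0, hy$koff0, hy$Ks), c(8.14e4, 0.54, 6.7))
  expect_identical(c(no$l0, no$d_on, no$d_off), c(0.3, 0.75, 0.75))
  expect_identical(c(no$sigma_on, no$sigma_off), c(0.51, 0.17))
})

test_that("parameter validation enforces the documented constraints", {
  expect_error(adhesion_params(Ks = 2.9, l0 = 0.8, kon0 = 5e4, koff0 = 1),
               "l0 < d_on")
  expect_error(adhesion_params(Ks = -1, kon0 = 5e4, koff0 = 1), ">= 0")
  expect_error(adhesion_params(Ks = 2.9, kon0 = 1e8, koff0 = 1),
               "outside the documented range")
})

test_that("stochastic update obeys the degenerate limits", {
  cap <- list(center = c(0, -9), radius = 9)  # surface at z = 0
  verts <- cbind(seq(-1, 1, length.out = 11), rep(0.3, 11))
  p_on0 <- adhesion_params(Ks = 2.9, kon0 = 0, koff0 = 1,
                           check_ranges = FALSE)
  reg <- bond_registry(11)
  st <- list(form = rng_stream(1), diss = rng_stream(2))
  for (k in 1:50)
    reg <- stochastic_update(reg, verts, cap, p_on0, 1e-3, st)
  expect_identical(bond_count(reg), 0L)  # kon0 = 0: no bonds ever form

  p_off0 <- adhesion_params(Ks = 2.9, kon0 = 5.42e4, koff0 = 0,
                            check_ranges = FALSE)
  p_off0$sigma_off <- 0
  reg <- bond_registry(11)
  for (k in 1:50)
    reg <- stochastic_update(reg, verts, cap, p_off0, 1e-3, st)
  expect_identical(bond_count(reg), 11L)  # koff = 0, l < d_off: permanent
})

test_that("fixed-gap bound fraction matches the two-state Markov chain", {
  # vertex held at l = l0: rates constant, so the per-step chain has
  # stationary bound fraction P_on / (P_on + P_off)
  dt <- 2e-3
  p <- adhesion_params(Ks = 2.9, kon0 = 30, koff0 = 70,
                       check_ranges = FALSE)
  cap <- list(center = c(0, -9), radius = 9)
  vert <- matrix(c(0, p$l0), 1, 2)
  st <- list(form = rng_stream(11), diss = rng_stream(12))
  reg <- bond_registry(1)
  n <- 4e4
  bound <- logical(n)
  for (k in seq_len(n)) {
    reg <- stochastic_update(reg, vert, cap, p, dt, st)
    bound[k] <- reg$bonded[1]
  }
  pon <- formation_probability(p$kon0, dt)
  poff <- formation_probability(p$koff0, dt)
  expected <- pon / (pon + poff)
  expect_lt(abs(mean(bound[-(1:500)]) / expected - 1), 0.02)
})

test_that("bond forces are the exact negative gradient of U_adh", {
  p <- adhesion_preset("hypoxia")
  # single bond stretched by 0.1 um with the hypoxia Ks: |F| = 0.67 pN
  reg <- bond_registry(1)
  reg$bonded[1] <- TRUE
  reg$anchor[1, ] <- c(0, 0)
  out <- bond_forces(reg, matrix(c(0, p$l0 + 0.1), 1), p)
  expect_equal(sqrt(sum(out$forces^2)), 6.7 * 0.1, tolerance = 1e-12)
  expect_equal(out$forces, -out$reaction)
  # zero at the equilibrium length
  out0 <- bond_forces(reg, matrix(c(0, p$l0), 1), p)
  expect_equal(max(abs(out0$forces)), 0)
  # finite-difference check over a random bond set
  set.seed(5)
  n <- 12
  reg <- bond_registry(n)
  reg$bonded[] <- TRUE
  reg$anchor <- matrix(rnorm(2 * n), n, 2)
  x <- reg$anchor + matrix(rnorm(2 * n, sd = 0.3), n, 2)
  out <- bond_forces(reg, x, p)
  h <- 1e-7
  for (i in sample(n, 4)) {
    for (d in 1:2) {
      xp <- x; xp[i, d] <- xp[i, d] + h
      xm <- x; xm[i, d] <- xm[i, d] - h
      fd <- -(bond_forces(reg, xp, p)$energy -
                bond_forces(reg, xm, p)$energy) / (2 * h)
      expect_lt(abs(fd - out$forces[i, d]) /
                  max(abs(fd), abs(out$forces[i, d])), 1e-6)
    }
  }
})

test_that("Morse aggregation forces vanish at r0 and beyond the cutoff", {
  p <- aggregation_params(De = 0.5)
  A <- matrix(c(0, 0), 1)
  B <- matrix(c(p$r0, 0), 1)
  out <- morse_aggregation_forces(list(A, B), p)
  expect_lt(max(abs(out$forces[[1]])), 1e-12)
  Bfar <- matrix(c(p$cutoff + 0.01, 0), 1)
  out2 <- morse_aggregation_forces(list(A, Bfar), p)
  expect_identical(max(abs(out2$forces[[1]])), 0)
  # attraction beyond r0, repulsion below, equal and opposite
  Bmid <- matrix(c(p$r0 + 0.2, 0), 1)
  out3 <- morse_aggregation_forces(list(A, Bmid), p)
  expect_gt(out3$forces[[1]][1, 1], 0)  # pulled towards +x neighbour
  expect_equal(out3$forces[[1]], -out3$forces[[2]])
  Bnear <- matrix(c(p$r0 - 0.1, 0), 1)
  out4 <- morse_aggregation_forces(list(A, Bnear), p)
  expect_lt(out4$forces[[1]][1, 1], 0)
  # disabled flag returns zero forces
  pd <- aggregation_params(De = 0.5, enabled = FALSE)
  expect_identical(morse_aggregation_forces(list(A, Bmid), pd)$energy, 0)
})

test_that("a resting doublet stays aggregated at the default well depth", {
  cfg <- doublet_config(De = aggregation_params()$De, enabled = TRUE)
  st <- initialize_state(cfg)
  gap0 <- abs(diff(colMeans(matrix(st$kstate$pos[, 2], nrow = 40))))
  r <- run_sim(st, 1.0, record_dt = 0.1)
  dz <- abs(r$trajectory$comz[, 2] - r$trajectory$comz[, 1])
  expect_true(all(dz < gap0 + 0.5))  # held together by the Morse well
  # energetic argument: the contact well is hundreds of kBT deep, thermal
  # escape over 1 s is negligible
  expect_lt(tail(dz, 1), gap0 + 0.2)
})

test_that("disabling aggregation gives dynamics identical to De = 0", {
  cfg1 <- doublet_config(De = 0, enabled = TRUE)
  cfg2 <- doublet_config(De = 0.4, enabled = FALSE)
  r1 <- run_sim(initialize_state(cfg1), 0.2, record_dt = 0.05)
  r2 <- run_sim(initialize_state(cfg2), 0.2, record_dt = 0.05)
  expect_identical(r1$state$kstate$pos, r2$state$kstate$pos)
})
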