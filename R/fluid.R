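# Particle-based solvent: DPD pairwise forces (conservative + dissipative +
# random, fluctuation-dissipation consistent), periodic/Couette boxes with
# bounce-back walls, and the reduced-mode fluid-membrane coupling.

#' DPD parameter set
#'
#' Soft-particle solvent parameters in DPD units (cutoff r_c = 1, particle
#' mass 1, k_B = 1). The constructor enforces the fluctuation-dissipation
#' relation sigma^2 = 2 gamma kBT.
#'
#' @param a conservative repulsion coefficient.
#' @param gamma dissipative coefficient.
#' @param kBT thermal energy.
#' @param sigma random-force coefficient; computed from gamma and kBT when
#'   omitted, rejected if inconsistent.
#' @param rc cutoff radius.
#' @param dt timestep.
#' @param exponent weight-function exponent (w = (1 - r/rc)^exponent).
#' @param density number density (particles per rc^2 in the 2D box).
#' @return a `dpd_params` list.
#' @export
dpd_params <- function(a = 25, gamma = 4.5, kBT = 1, sigma = NULL, rc = 1,
                       dt = 0.01, exponent = 1, density = 4) {
  stopifnot(rc > 0, dt > 0, gamma > 0, kBT > 0)
  target <- sqrt(2 * gamma * kBT)
  if (is.null(sigma)) sigma <- target
  if (abs(sigma^2 - 2 * gamma * kBT) > 1e-9 * max(1, sigma^2))
    stop(sprintf(paste0("fluctuation-dissipation violated: sigma^2 = %.6g ",
                        "but 2 gamma kBT = %.6g"), sigma^2, 2 * gamma * kBT))
  structure(list(a = a, gamma = gamma, sigma = sigma, kBT = kBT, rc = rc,
                 dt = dt, exponent = exponent, density = density),
            class = "dpd_params")
}

#' Channel domain
#'
#' Couette microchannel: periodic in x (and y in 3D), bounce-back walls at
#' z = 0 (stationary) and z = h (moving at `U_top`).
#'
#' @param L channel length, um.
#' @param h channel height, um (default 20).
#' @param U_top top-wall speed, um/s.
#' @param Ly channel width for 3D setups, um (unused in 2D mode).
#' @return a `channel_domain` list.
#' @export
channel_domain <- function(L, h = 20, U_top = 0, Ly = NULL) {
  stopifnot(h > 0, L > 0, U_top >= 0)
  structure(list(L = L, h = h, U_top = U_top, Ly = Ly),
            class = "channel_domain")
}

#' Analytic Couette profile
#'
#' u(z) = U_top z / h: the linear shear profile between a stationary bottom
#' wall and a top wall moving at `U_top`.
#'
#' @param z heights, um.
#' @param U_top top-wall speed, um/s.
#' @param h channel height, um.
#' @return velocities, um/s.
#' @export
couette_profile <- function(z, U_top, h) U_top * z / h

#' DPD pair forces for a configuration
#'
#' Single evaluation of the DPD force triplet on a set of particles
#' (periodic images not applied): used to verify Newton's third law, the
#' cutoff, and finite forces at zero separation.
#'
#' @param positions n x 2 matrix.
#' @param velocities n x 2 matrix.
#' @param params a [dpd_params()].
#' @param seed RNG seed for the symmetric per-pair noise.
#' @return n x 2 force matrix.
#' @export
dpd_pair_forces <- function(positions, velocities, params, seed = 1L) {
  stopifnot(inherits(params, "dpd_params"))
  out <- dpd_forces_once(positions, velocities, params$a, params$gamma,
                         params$sigma, params$kBT, params$dt,
                         as.integer(seed))
  out$forces
}

#' Equilibrium DPD box run
#'
#' Fully periodic box at rest; reports the measured kinetic temperature
#' (from the wall-normal velocity component) and the total-momentum drift.
#'
#' @param params a [dpd_params()].
#' @param Lx,Lz box dimensions in rc units.
#' @param n_steps,warmup step counts.
#' @param seed RNG seed.
#' @return list with `temperature`, `momentum`, `max_pair_force_sum`.
#' @export
dpd_equilibrium <- function(params, Lx = 10, Lz = 10, n_steps = 4000,
                            warmup = 1000, seed = 1L) {
  run_dpd_box(Lx, Lz, params$density, params$a, params$gamma, params$kBT,
              params$dt, as.integer(n_steps), as.integer(warmup), 0, 0L,
              10L, as.integer(seed))
}

#' Couette DPD run
#'
#' Periodic-in-x box with frozen-particle walls and bounce-back at z = 0
#' (at rest) and z = Lz (moving at `U_top`); returns the time-averaged
#' velocity profile for comparison with [couette_profile()].
#'
#' @param params a [dpd_params()].
#' @param Lx,Lz box size in rc units.
#' @param U_top top-wall speed in DPD units.
#' @param n_steps,warmup step counts.
#' @param nzbins profile bins.
#' @param seed RNG seed.
#' @return list with `profile_z`, `profile_u`, `temperature`.
#' @export
dpd_couette <- function(params, Lx = 16, Lz = 10, U_top = 1,
                        n_steps = 12000, warmup = 4000, nzbins = 10L,
                        seed = 1L) {
  run_dpd_box(Lx, Lz, params$density, params$a, params$gamma, params$kBT,
              params$dt, as.integer(n_steps), as.integer(warmup), U_top, 1L,
              as.integer(nzbins), as.integer(seed))
}

#' Reduced-mode fluid-membrane coupling forces
#'
#' In the 2D reduced mode the solvent acts on membrane vertices through a
#' Langevin-type coupling to the analytic Couette background: per-vertex
#' drag zeta_v (u_bg - v) plus fluctuation-dissipation-consistent thermal
#' noise, and a near-surface deformability-lift force on each cell. The
#' equal-and-opposite reaction on the (implicit) fluid is returned as the
#' negated column sums.
#'
#' @param positions n x 2 vertex positions.
#' @param velocities n x 2 vertex velocities.
#' @param domain a [channel_domain()].
#' @param constants reduced-mode constants, see [model_constants()].
#' @param noise include the stochastic part (deterministic drag otherwise).
#' @param seed,step RNG stream coordinates when `noise = TRUE`.
#' @return list with `membrane` (n x 2 forces, pN) and `fluid_reaction`.
#' @export
couple_membrane <- function(positions, velocities, domain,
                            constants = model_constants(), noise = FALSE,
                            seed = 1L, step = 0L) {
  if (any(positions[, 2] < 0) || any(positions[, 2] > domain$h))
    stop("membrane outside the channel domain")
  ubg <- cbind(couette_profile(positions[, 2], domain$U_top, domain$h), 0)
  f <- constants$zeta_v * (ubg - velocities)
  if (noise) {
    sig <- constants$zeta_v *
      sqrt(2 * constants$D_cell * constants$nv / constants$dt)
    rs <- rng_stream(as.integer(seed) + as.integer(step))
    f <- f + sig * matrix(stats::qnorm(draw_uniform(rs, 2 * nrow(f))),
                          ncol = 2)
  }
  list(membrane = f, fluid_reaction = -colSums(f))
}
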