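# Stochastic receptor-ligand adhesion between RBC membrane vertices and the
# macrophage surface: distance-dependent formation/dissociation rates
# (Bell/Dembo form), per-timestep Monte-Carlo bond updates, harmonic bond
# forces, and Morse-potential RBC-RBC aggregation.

# Literature ranges used for validation (physical units: pN/um == uN/m, um,
# 1/s). The equilibrium bond length used by the model (0.3 um) sits at the
# edge of the literature interval, so the admissible interval includes it.
.adhesion_ranges <- list(
  Ks = c(1, 1e4), l0 = c(0, 0.3), d_on = c(0, 1), d_off = c(0, 1),
  sigma_on = c(0.5, 0.6), sigma_off = c(0.05, 0.75),
  kon0 = c(1e3, 1.2e6), koff0 = c(0.5, 300)
)

#' Adhesion parameter set
#'
#' Parameters of the stochastic bond model in physical units: adhesion
#' strength `Ks` (uN/m), equilibrium bond length `l0` (um), formation and
#' dissociation cutoffs `d_on`, `d_off` (um), effective formation/rupture
#' strengths `sigma_on`, `sigma_off` (uN/m), and unstressed formation and
#' dissociation rates `kon0`, `koff0` (1/s).
#'
#' @param Ks adhesion (bond spring) strength, uN/m.
#' @param l0 equilibrium bond length, um (must be < `d_on`).
#' @param d_on bond formation cutoff, um.
#' @param d_off bond dissociation cutoff, um.
#' @param sigma_on effective formation strength, uN/m.
#' @param sigma_off effective rupture strength, uN/m.
#' @param kon0 formation rate at l = l0, 1/s.
#' @param koff0 dissociation rate at l = l0, 1/s.
#' @param kBT thermal energy, pN um.
#' @param check_ranges validate against the documented literature ranges.
#' @return an `adhesion_params` list.
#' @seealso [adhesion_preset()] for the calibrated oxygenation presets.
#' @export
adhesion_params <- function(Ks, l0 = 0.3, d_on = 0.75, d_off = 0.75,
                            sigma_on = 0.51, sigma_off = 0.17,
                            kon0, koff0, kBT = .kBT, check_ranges = TRUE) {
  p <- list(Ks = Ks, l0 = l0, d_on = d_on, d_off = d_off,
            sigma_on = sigma_on, sigma_off = sigma_off, kon0 = kon0,
            koff0 = koff0, kBT = kBT)
  num <- vapply(p, is.numeric, TRUE)
  if (!all(num)) stop("all adhesion parameters must be numeric")
  if (any(unlist(p) < 0)) stop("adhesion rates, strengths and lengths must be >= 0")
  if (l0 >= d_on) stop("require l0 < d_on")
  if (check_ranges) {
    for (nm in names(.adhesion_ranges)) {
      val <- p[[sub("^sigma_", "sigma_", nm)]]
      val <- switch(nm, Ks = Ks, l0 = l0, d_on = d_on, d_off = d_off,
                    sigma_on = sigma_on, sigma_off = sigma_off,
                    kon0 = kon0, koff0 = koff0)
      rg <- .adhesion_ranges[[nm]]
      if (val < rg[1] - 1e-12 || val > rg[2] + 1e-12)
        stop(sprintf("%s = %g outside the documented range [%g, %g]",
                     nm, val, rg[1], rg[2]))
    }
  }
  structure(p, class = "adhesion_params")
}

#' Calibrated adhesion presets
#'
#' Ships the calibrated parameter sets for sickle RBCs under normoxia
#' (kon0 = 5.42e4 1/s, koff0 = 2.71 1/s, Ks = 2.9 uN/m) and hypoxia
#' (kon0 = 8.14e4 1/s, koff0 = 0.54 1/s, Ks = 6.7 uN/m), and the
#' normal-RBC preset whose Ks was fitted with [calibrate_adhesion()] against
#' the observed ~500 um/s detachment velocity (normoxia kinetic rates).
#'
#' @param name `"normoxia"`, `"hypoxia"` or `"normal"`.
#' @return an [adhesion_params()] object.
#' @export
adhesion_preset <- function(name = c("normoxia", "hypoxia", "normal")) {
  name <- match.arg(name)
  switch(name,
    normoxia = adhesion_params(Ks = 2.9, kon0 = 5.42e4, koff0 = 2.71),
    hypoxia = adhesion_params(Ks = 6.7, kon0 = 8.14e4, koff0 = 0.54),
    normal = adhesion_params(Ks = 1.97, kon0 = 5.42e4, koff0 = 2.71))
}

#' Bond formation rate
#'
#' k_on(l) = kon0 exp(-sigma_on (l - l0)^2 / (2 kB T)): maximal at the
#' equilibrium length and even in (l - l0).
#'
#' @param l bond (gap) length, um; vectorised.
#' @param p an [adhesion_params()].
#' @return rate in 1/s.
#' @export
formation_rate <- function(l, p) {
  stopifnot(all(l >= 0))
  p$kon0 * exp(-p$sigma_on * (l - p$l0)^2 / (2 * p$kBT))
}

#' Bond dissociation rate
#'
#' k_off(l) = koff0 exp(-sigma_off (l - l0)^2 / (2 kB T)).
#'
#' @inheritParams formation_rate
#' @return rate in 1/s.
#' @export
dissociation_rate <- function(l, p) {
  stopifnot(all(l >= 0))
  p$koff0 * exp(-p$sigma_off * (l - p$l0)^2 / (2 * p$kBT))
}

#' Per-step formation/dissociation probability
#'
#' P = 1 - exp(-k dt); in (0, 1) and monotone in both arguments.
#'
#' @param k rate, 1/s.
#' @param dt timestep, s.
#' @return probability.
#' @export
formation_probability <- function(k, dt) {
  stopifnot(dt > 0, all(k >= 0))
  -expm1(-k * dt)
}

#' Seeded uniform random stream
#'
#' Dedicated RNG stream for bond-formation / bond-dissociation draws; an
#' unseeded stream is a configuration error in the stochastic update.
#'
#' @param seed integer seed.
#' @return an object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  if (missing(seed) || !is.finite(seed)) stop("rng_stream requires a seed")
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  env$n_drawn <- 0
  class(env) <- "rng_stream"
  env
}

#' @export
draw_uniform <- function(stream, n) {
  UseMethod("draw_uniform")
}

#' Draw uniforms from a dedicated stream
#' @param stream an [rng_stream()].
#' @param n number of draws.
#' @return numeric vector in (0, 1).
#' @export
draw_uniform.rng_stream <- function(stream, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, envir = globalenv())
  u <- runif(n)
  stream$state <- get(".Random.seed", globalenv())
  stream$n_drawn <- stream$n_drawn + n
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  u
}

#' Create an empty bond registry
#'
#' @param n_vertices number of RBC vertices that can carry a bond (at most
#'   one live bond per vertex).
#' @return a `bond_registry` list with per-vertex bond state.
#' @export
bond_registry <- function(n_vertices) {
  structure(list(bonded = rep(FALSE, n_vertices),
                 anchor = matrix(NA_real_, n_vertices, 2),
                 formed_at = rep(NA_real_, n_vertices)),
            class = "bond_registry")
}

#' Bond count of a registry
#' @param registry a [bond_registry()].
#' @return integer number of live bonds.
#' @export
bond_count <- function(registry) sum(registry$bonded)

# Nearest point and gap from 2D points to a circular cap surface.
nearest_on_cap <- function(pts, cap) {
  d <- cbind(pts[, 1] - cap$center[1], pts[, 2] - cap$center[2])
  dist <- sqrt(rowSums(d^2))
  gap <- dist - cap$radius
  sc <- cap$radius / pmax(dist, 1e-12)
  list(anchor = cbind(cap$center[1] + d[, 1] * sc,
                      cap$center[2] + d[, 2] * sc),
       gap = gap)
}

#' One Monte-Carlo step of bond formation/dissociation
#'
#' Applies the per-step stochastic rules: an unbonded vertex within `d_on`
#' of the macrophage surface forms a bond iff P_on > lambda1; a live bond
#' dissociates iff (l < d_off and P_off > lambda2), and ruptures
#' deterministically once stretched to l >= d_off. Uniform deviates are
#' consumed from the two dedicated seeded streams.
#'
#' @param registry a [bond_registry()].
#' @param rbc_vertices n x 2 matrix of vertex positions.
#' @param macrophage_surface list with `center` (length 2) and `radius`.
#' @param p an [adhesion_params()].
#' @param dt timestep, s.
#' @param streams list with `form` and `diss` [rng_stream()]s.
#' @param time current time (recorded on newly formed bonds).
#' @return the updated registry.
#' @export
stochastic_update <- function(registry, rbc_vertices, macrophage_surface, p,
                              dt, streams, time = 0) {
  if (!inherits(streams$form, "rng_stream") ||
      !inherits(streams$diss, "rng_stream"))
    stop("stochastic_update requires seeded `form` and `diss` rng streams")
  np <- nearest_on_cap(rbc_vertices, macrophage_surface)
  n <- nrow(rbc_vertices)
  lam1 <- draw_uniform(streams$form, n)
  lam2 <- draw_uniform(streams$diss, n)
  bonded <- registry$bonded
  free <- !bonded  # frozen at step start: no break-and-reform in one step
  # dissociation for live bonds (length measured to the stored anchor)
  if (any(bonded)) {
    dl <- rbc_vertices[bonded, , drop = FALSE] -
      registry$anchor[bonded, , drop = FALSE]
    l <- sqrt(rowSums(dl^2))
    poff <- formation_probability(dissociation_rate(l, p), dt)
    break_now <- l >= p$d_off | poff > lam2[bonded]
    idx <- which(bonded)[break_now]
    registry$bonded[idx] <- FALSE
    registry$anchor[idx, ] <- NA_real_
    registry$formed_at[idx] <- NA_real_
  }
  # formation for vertices that entered the step unbonded, within d_on
  l <- pmax(np$gap, 0)
  pon <- formation_probability(formation_rate(l, p), dt)
  form_now <- free & l < p$d_on & pon > lam1
  registry$bonded[form_now] <- TRUE
  registry$anchor[form_now, ] <- np$anchor[form_now, , drop = FALSE]
  registry$formed_at[form_now] <- time
  registry
}

#' Adhesive bond forces
#'
#' Harmonic bond force of magnitude Ks |l - l0| along each bond, attractive
#' beyond l0 and repulsive below it, with the equal-and-opposite reaction on
#' the macrophage anchor. The forces are the exact negative gradient of
#' U_adh = 0.5 sum Ks (l - l0)^2.
#'
#' @param registry a [bond_registry()].
#' @param rbc_vertices n x 2 vertex positions, um.
#' @param p an [adhesion_params()].
#' @return list with `forces` (n x 2, pN), `reaction` (n x 2, on anchors)
#'   and `energy` (pN um).
#' @export
bond_forces <- function(registry, rbc_vertices, p) {
  n <- nrow(rbc_vertices)
  f <- matrix(0, n, 2)
  energy <- 0
  b <- registry$bonded
  if (any(b)) {
    dl <- rbc_vertices[b, , drop = FALSE] - registry$anchor[b, , drop = FALSE]
    l <- sqrt(rowSums(dl^2))
    energy <- 0.5 * sum(p$Ks * (l - p$l0)^2)
    fm <- -p$Ks * (l - p$l0) / pmax(l, 1e-12)
    f[b, ] <- dl * fm
  }
  list(forces = f, reaction = -f, energy = energy)
}

#' Morse aggregation parameters
#'
#' Intercellular Morse potential D_e (exp(-2 beta (r - r0)) -
#' 2 exp(-beta (r - r0))) applied between vertices of distinct sickle RBCs
#' in proximity, generating the aggregation (rouleau-forming) force.
#'
#' @param De well depth, pN um.
#' @param beta inverse interaction range, 1/um.
#' @param r0 equilibrium separation, um.
#' @param cutoff interaction cutoff, um (> r0).
#' @param enabled logical flag.
#' @return an `aggregation_params` list.
#' @export
aggregation_params <- function(De = 0.25, beta = 3.9, r0 = 0.3, cutoff = 1.2,
                               enabled = TRUE) {
  stopifnot(De >= 0, cutoff > r0, beta > 0)
  structure(list(De = De, beta = beta, r0 = r0, cutoff = cutoff,
                 enabled = isTRUE(enabled)),
            class = "aggregation_params")
}

#' Morse aggregation forces between RBCs
#'
#' Pairwise Morse forces between vertices of distinct cells; zero beyond the
#' cutoff, zero at r = r0, equal and opposite within each pair.
#'
#' @param rbc_outlines list of n x 2 vertex matrices (one per cell).
#' @param p an [aggregation_params()].
#' @return list of force matrices matching `rbc_outlines`, plus `energy`.
#' @export
morse_aggregation_forces <- function(rbc_outlines, p) {
  stopifnot(inherits(p, "aggregation_params"))
  nc <- length(rbc_outlines)
  forces <- lapply(rbc_outlines, function(m) matrix(0, nrow(m), 2))
  energy <- 0
  if (!p$enabled || nc < 2) return(list(forces = forces, energy = energy))
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      out <- morse_pair_forces(rbc_outlines[[i]], rbc_outlines[[j]],
                               p$De, p$beta, p$r0, p$cutoff)
      forces[[i]] <- forces[[i]] + out$FA
      forces[[j]] <- forces[[j]] + out$FB
      energy <- energy + out$energy
    }
  }
  list(forces = forces, energy = energy)
}
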