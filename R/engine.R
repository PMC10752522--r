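# Simulation engine (2D reduced mode): configuration, initialisation,
# time stepping, restart, and unit/seed bookkeeping. The heavy loop lives in
# the C++ kernel; forces, adhesion kinetics and RNG streams are documented
# there and in the module files.

#' Reduced-mode model constants
#'
#' Numerical and physical constants of the 2D reduced mode (units um, s,
#' pN). `zeta_v` (per-vertex drag to the Couette background) and `UL` (the
#' dimensionless near-surface lift amplitude) are the two hydrodynamic
#' coupling constants of the reduced model; they were calibrated once
#' against the observed detachment velocity of the normoxia sickle preset
#' (~1000 um/s at the cap apex) and the observed no-contact flow threshold
#' (~500 um/s) respectively, and are not tuned per assay.
#'
#' @param ... overrides of individual constants.
#' @return list of constants.
#' @export
model_constants <- function(...) {
  con <- list(
    dt = 1e-4,        # s
    mass = 5e-5,      # pN s^2/um per vertex
    zeta_v = 1.05e-4, # pN s/um per vertex (calibrated, see vignette)
    kBT = .kBT,       # pN um at 310 K (bond kinetics)
    D_cell = 0.05,    # um^2/s whole-cell diffusivity the noise reproduces
    mu = .mu_plasma,  # pN s/um^2
    UL = 300,         # lift amplitude (calibrated, see vignette)
    nv = 40L,         # vertices per cell
    kedge = 60,       # pN/um contour spring (quasi-inextensible)
    kA = 600,         # pN/um global area stiffness
    kb_l0 = 0.6,      # um reference edge for bending stiffness mapping
    k_rep = 60, r_rep = 0.4,   # cell-cell steric
    k_mac = 60, d_rep = 0.3,   # cell-macrophage steric
    k_wall = 60, d_wall = 0.3, # wall steric
    touch_dist = 0.7           # um, aggregate adjacency threshold
  )
  ov <- list(...)
  con[names(ov)] <- ov
  con
}

# Moduli per membrane condition label.
condition_moduli <- function(condition) {
  base <- membrane_params()
  switch(condition,
    normal = base,
    sickle_normoxia = condition_params("normoxia", base, "sickle"),
    sickle_hypoxia = condition_params("hypoxia", base, "sickle"),
    stop("unknown membrane condition: ", condition))
}

default_adhesion_for <- function(condition) {
  switch(condition,
    normal = adhesion_preset("normal"),
    sickle_normoxia = adhesion_preset("normoxia"),
    sickle_hypoxia = adhesion_preset("hypoxia"))
}

#' Simulation configuration
#'
#' Assembles and validates a reduced-mode simulation: channel geometry (or
#' hematocrit-driven channel length), cell population, macrophage layout,
#' membrane condition, adhesion preset, aggregation, velocity schedule and
#' seeding. Velocities are specified "around the macrophages" (at cap-apex
#' height, as reported experimentally) and converted internally to the
#' top-wall speed.
#'
#' @param n_cells number of RBCs.
#' @param shape morphology name or vector (length `n_cells`).
#' @param hct target hematocrit (area fraction, in (0, 0.7]); sets the
#'   channel length L = n_cells A_cell / (hct h) unless `L` is given.
#' @param condition `"normal"`, `"sickle_normoxia"` or `"sickle_hypoxia"`.
#' @param adhesion an [adhesion_params()], preset name, or NULL for the
#'   condition default.
#' @param aggregation an [aggregation_params()] or NULL: enabled by default
#'   for hypoxic sickle cells, disabled otherwise.
#' @param macrophages data.frame with columns `x`, `radius` (um), or NULL to
#'   auto-place `n_macs` caps evenly; cap apex height is the cap radius plus
#'   centre height (centre sits at cap_height - radius).
#' @param n_macs number of macrophages when auto-placing.
#' @param mac_radius cap radius for auto-placed macrophages, um.
#' @param cap_height apex height of the caps, um (default 11).
#' @param h channel height, um.
#' @param L channel length override, um.
#' @param velocity scalar velocity (um/s, at cap-apex height) or a
#'   data.frame `time`, `v` for a step-wise schedule.
#' @param seed master seed (integer).
#' @param time_scaling multiplies reported times (accelerated-time
#'   relabeling; dynamics are unaffected).
#' @param z_range vertical placement band for cell centroids, or NULL for
#'   the full channel minus a wall margin.
#' @param placement optional data.frame `x`, `z`, `angle` giving explicit
#'   cell centroid positions and orientations (bypasses random placement).
#' @param constants [model_constants()] overrides (list).
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(n_cells, shape = "biconcave", hct = 0.02,
                              condition = c("sickle_hypoxia",
                                            "sickle_normoxia", "normal"),
                              adhesion = NULL, aggregation = NULL,
                              macrophages = NULL, n_macs = 2L,
                              mac_radius = 9, cap_height = 11, h = 20,
                              L = NULL, velocity = 150, seed = 1L,
                              time_scaling = 1, z_range = NULL,
                              placement = NULL, constants = list()) {
  condition <- match.arg(condition)
  stopifnot(n_cells >= 0)
  if (!is.null(hct) && (hct <= 0 || hct > 0.7))
    stop("hematocrit must lie in (0, 0.7]")
  con <- do.call(model_constants, constants)
  shapes <- rep_len(as.character(shape), max(n_cells, 1L))
  outline0 <- make_cell_outline("biconcave", con$nv)
  a_cell <- attr(outline0, "area")
  if (is.null(L)) {
    if (n_cells > 0) L <- n_cells * a_cell / (hct * h)
    else L <- 60
  }
  if (is.null(macrophages) && n_macs > 0) {
    macrophages <- data.frame(
      x = L * (seq_len(n_macs) - 0.5) / n_macs,
      radius = rep(mac_radius, n_macs))
  }
  if (is.null(macrophages))
    macrophages <- data.frame(x = numeric(0), radius = numeric(0))
  if (nrow(macrophages) > 0) {
    # validate each cap as a macrophage_spec (admissible radius, feasible cap)
    for (i in seq_len(nrow(macrophages)))
      macrophage_spec(radius = macrophages$radius[i], cap_height = cap_height,
                      base_center = c(macrophages$x[i], 0))
  }
  if (is.numeric(velocity) && length(velocity) == 1) {
    velocity <- data.frame(time = 0, v = velocity)
  }
  stopifnot(is.data.frame(velocity), all(velocity$v >= 0),
            !is.unsorted(velocity$time))
  if (!is.null(adhesion) && is.character(adhesion))
    adhesion <- adhesion_preset(adhesion)
  if (is.null(adhesion)) adhesion <- default_adhesion_for(condition)
  if (is.null(aggregation))
    aggregation <- aggregation_params(enabled = condition == "sickle_hypoxia")
  structure(list(
    n_cells = as.integer(n_cells), shapes = shapes, hct = hct,
    condition = condition, adhesion = adhesion, aggregation = aggregation,
    macrophages = macrophages, cap_height = cap_height, h = h, L = L,
    velocity = velocity, seed = as.integer(seed),
    time_scaling = time_scaling, z_range = z_range, placement = placement,
    constants = con, a_cell = a_cell),
    class = "simulation_config")
}

# Apex height of the macrophage layout (used to convert reported velocities).
apex_height <- function(config) {
  if (nrow(config$macrophages) == 0) return(config$h)
  config$cap_height
}

# Reported (cap-apex) velocity -> top-wall speed.
v_to_Utop <- function(v, config) v * config$h / apex_height(config)

# Velocity schedule in kernel form (top-wall speeds).
schedule_for <- function(config) {
  list(t = config$velocity$time, U = v_to_Utop(config$velocity$v, config))
}

# 2D macrophage caps as a matrix (cx, cz, R); centre height cap_height - R.
macs_matrix <- function(config) {
  m <- config$macrophages
  if (nrow(m) == 0) return(matrix(0, 0, 3))
  cbind(m$x, config$cap_height - m$radius, m$radius)
}

#' Initialize a simulation state
#'
#' Builds cell outlines, places cells without overlap (rejection sampling
#' from the master seed's init stream), assigns Couette velocities, and
#' returns a runnable state. Cells are kept clear of walls and macrophage
#' caps; an impossible packing is reported with the achievable hematocrit.
#'
#' @param config a [simulation_config()].
#' @return a `splenosim_state`.
#' @export
initialize_state <- function(config) {
  con <- config$constants
  nv <- con$nv
  macs <- macs_matrix(config)
  n <- config$n_cells * nv
  pos <- matrix(0, max(n, 0), 2)
  l0 <- numeric(max(n, 0)); th0 <- numeric(max(n, 0))
  A0 <- numeric(config$n_cells)
  kbend <- numeric(config$n_cells); Es <- numeric(config$n_cells)
  moduli <- condition_moduli(config$condition)
  eb_pnum <- moduli$E_b * 1e18
  aeq <- sqrt(config$a_cell / pi)
  oldseed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldseed)) assign(".Random.seed", oldseed,
                                        envir = globalenv()))
  set.seed(config$seed)
  placed <- list()
  rbs <- numeric(0)
  zr <- config$z_range
  for (c in seq_len(config$n_cells)) {
    out <- make_cell_outline(config$shapes[c], nv, area = config$a_cell,
                             seed = config$seed + c)
    rb <- attr(out, "radius")
    ok <- FALSE
    if (!is.null(config$placement)) {
      pl <- config$placement[c, ]
      ang <- pl$angle
      rot <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2)
      o <- out %*% rot
      placed[[c]] <- list(v = cbind(o[, 1] + pl$x, o[, 2] + pl$z),
                          c = c(pl$x, pl$z))
      rbs <- c(rbs, rb)
      ok <- TRUE
    }
    for (try in if (ok) integer(0) else seq_len(4000)) {
      ang <- runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2)
      o <- out %*% rot
      hh <- diff(range(o[, 2])) / 2
      zlim <- if (is.null(zr)) c(0.8 + hh, config$h - 0.8 - hh)
              else c(max(zr[1], 0.8 + hh), min(zr[2], config$h - 0.8 - hh))
      if (zlim[1] >= zlim[2]) next
      cx <- runif(1, 0, config$L)
      cz <- runif(1, zlim[1], zlim[2])
      cand <- cbind(o[, 1] + cx, o[, 2] + cz)
      # macrophage clearance (vertex level)
      clear <- TRUE
      if (nrow(macs) > 0) {
        for (mi in seq_len(nrow(macs))) {
          dx <- cand[, 1] - macs[mi, 1]
          dx <- dx - config$L * round(dx / config$L)
          if (any(dx^2 + (cand[, 2] - macs[mi, 2])^2 <
                  (macs[mi, 3] + 0.5)^2)) { clear <- FALSE; break }
        }
      }
      if (clear && length(placed) > 0) {
        for (pi in seq_along(placed)) {
          dx <- cx - placed[[pi]]$c[1]
          dx <- dx - config$L * round(dx / config$L)
          if (dx^2 + (cz - placed[[pi]]$c[2])^2 <
              (rb + rbs[pi] + 0.4)^2) { clear <- FALSE; break }
        }
      }
      if (clear) {
        placed[[c]] <- list(v = cand, c = c(cx, cz))
        rbs <- c(rbs, rb)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      ach <- (c - 1) * config$a_cell / (config$L * config$h)
      stop(sprintf(paste0("could not place cell %d of %d without overlap; ",
                          "achievable hematocrit in this geometry is about ",
                          "%.3f"), c, config$n_cells, ach))
    }
    idx <- ((c - 1) * nv + 1):(c * nv)
    pos[idx, ] <- placed[[c]]$v
    # reference geometry of the resting outline (rotation invariant)
    e <- out[c(2:nv, 1), ] - out
    l0[idx] <- sqrt(rowSums(e^2))
    a <- out - out[c(nv, 1:(nv - 1)), ]
    b <- e
    th0[idx] <- atan2(a[, 1] * b[, 2] - a[, 2] * b[, 1],
                      rowSums(a * b))
    A0[c] <- attr(out, "area")
    kbend[c] <- eb_pnum / con$kb_l0
    Es[c] <- moduli$E_s
  }
  sched <- schedule_for(config)
  U0 <- sched$U[1]
  # explicitly placed cells (assay setups) start at rest; randomly seeded
  # suspensions start advected with the local Couette flow
  vel <- if (n == 0) matrix(0, 0, 2)
         else if (!is.null(config$placement)) matrix(0, n, 2)
         else cbind(couette_profile(pos[, 2], U0, config$h), 0)
  kstate <- list(pos = pos, vel = vel, nv = nv, l0 = l0, theta0 = th0,
                 A0 = A0, bond_on = integer(max(n, 0)),
                 bond_ax = numeric(max(n, 0)), bond_az = numeric(max(n, 0)),
                 bond_t = numeric(max(n, 0)), time = 0, step = 0)
  structure(list(kstate = kstate, config = config, kbend = kbend, Es = Es,
                 aeq = aeq),
            class = "splenosim_state")
}

kernel_params <- function(state) {
  config <- state$config
  con <- config$constants
  adh <- config$adhesion
  agg <- config$aggregation
  list(kedge = con$kedge, kA = con$kA, mass = con$mass,
       zeta_v = con$zeta_v, kBT = con$kBT, dt = con$dt, mu = con$mu,
       UL = con$UL, aeq = state$aeq, L = config$L, h = config$h,
       adhesion_on = as.integer(nrow(config$macrophages) > 0),
       Ks = adh$Ks, l0b = adh$l0, don = adh$d_on, doff = adh$d_off,
       son = adh$sigma_on, soff = adh$sigma_off, kon0 = adh$kon0,
       koff0 = adh$koff0,
       agg_on = as.integer(agg$enabled), De = agg$De, beta = agg$beta,
       r0b = agg$r0, rcut = agg$cutoff,
       k_rep = con$k_rep, r_rep = con$r_rep, k_mac = con$k_mac,
       d_rep = con$d_rep, k_wall = con$k_wall, d_wall = con$d_wall,
       touch_dist = con$touch_dist,
       macs = macs_matrix(config),
       kbend = state$kbend, Es = state$Es, fluid_on = 1L,
       # per-vertex noise amplitude chosen so the cell centre-of-mass
       # diffusivity matches the physical RBC value D_cell (the
       # fluctuation-dissipation pairing with the calibrated desk-scale drag
       # would inflate Brownian dispersion ~25-fold)
       sigF = con$zeta_v * sqrt(2 * con$D_cell * con$nv / con$dt),
       # speed clamp: numerical safeguard against unresolved post-rupture
       # flight; far above any physical velocity in the channel
       vcap = 1.5 * max(v_to_Utop(config$velocity$v, config)) + 2000)
}

#' Advance a simulation
#'
#' Runs the kernel for `duration` seconds of simulated time, recording
#' snapshots every `record_dt`. Returns the advanced state and the recorded
#' trajectory chunk. Identical config + seed gives bitwise-identical
#' trajectories; a saved state continues exactly (counter-based RNG).
#'
#' @param state a `splenosim_state`.
#' @param duration simulated time, s.
#' @param record_dt snapshot interval, s (0 to disable recording).
#' @return list with `state` and `trajectory`.
#' @export
run_sim <- function(state, duration, record_dt = 0.01) {
  config <- state$config
  con <- config$constants
  n_steps <- max(1L, as.integer(round(duration / con$dt)))
  rec <- if (record_dt > 0) max(1L, as.integer(round(record_dt / con$dt)))
         else 0L
  sched <- schedule_for(config)
  out <- run_reduced2d(state$kstate, kernel_params(state), sched$t, sched$U,
                       n_steps, rec, config$seed)
  new_state <- state
  new_state$kstate <- out$state
  traj <- NULL
  if (rec > 0) {
    sn <- out$snapshots
    macs <- macs_matrix(config)
    traj <- structure(list(
      t = sn$t * config$time_scaling, t_sim = sn$t,
      comx = sn$comx, comz = sn$comz, speed = sn$speed, nb = sn$nb,
      gapmin = sn$gapmin, cluster = sn$cluster,
      macs = macs, h = config$h, L = config$L,
      schedule = config$velocity, apex = apex_height(config),
      condition = config$condition, time_scaling = config$time_scaling,
      d_on = config$adhesion$d_on,
      config_hash = config_hash(config)),
      class = "splenosim_trajectory")
  }
  list(state = new_state, trajectory = traj, area = out$area)
}

#' Single engine step
#'
#' Advances one timestep (no recording); mainly a building block and a
#' testing surface - assays use [run_sim()].
#'
#' @param state a `splenosim_state`.
#' @param n_steps number of steps.
#' @return the advanced state.
#' @export
sim_step <- function(state, n_steps = 1L) {
  run_sim(state, duration = n_steps * state$config$constants$dt,
          record_dt = 0)$state
}

#' Save / load a simulation state for restart
#'
#' A reloaded state continues bitwise-identically (the RNG is a pure
#' function of the master seed and the global step counter).
#'
#' @param state a `splenosim_state`.
#' @param path file path.
#' @return `load_state` returns the state.
#' @export
save_state <- function(state, path) {
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) readRDS(path)

#' Concatenate trajectory chunks
#' @param ... `splenosim_trajectory` objects from consecutive runs.
#' @return a single trajectory.
#' @export
traj_bind <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, TRUE)]
  out <- parts[[1]]
  for (p in parts[-1]) {
    out$t <- c(out$t, p$t)
    out$t_sim <- c(out$t_sim, p$t_sim)
    for (f in c("comx", "comz", "speed", "nb", "gapmin", "cluster"))
      out[[f]] <- rbind(out[[f]], p[[f]])
  }
  out
}

# Reported bulk ("around the macrophages") velocity at given times.
bulk_velocity_at <- function(traj, t_sim) {
  sched <- traj$schedule
  idx <- findInterval(t_sim, sched$time)
  idx[idx < 1] <- 1
  sched$v[idx]
}

# Tiny rolling-polynomial hash over the serialized config (no external
# digest dependency; used only to label outputs).
config_hash <- function(config) {
  b <- as.integer(serialize(config, NULL))
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483629
  sprintf("%08x", h)
}
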