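# Virtual assays: reproducible, replicate-aware experiments built on the
# reduced-mode engine. All velocities are reported "around the macrophages"
# (at cap-apex height). Paired designs reuse identical seeds so differences
# isolate the manipulated factor.

condition_for_preset <- function(preset) {
  switch(preset, normal = "normal", normoxia = "sickle_normoxia",
         hypoxia = "sickle_hypoxia")
}

# Single adhered cell on the upstream shoulder of one cap.
single_cell_config <- function(condition, adhesion, velocity, seed,
                               mac_radius = 9, shape = "biconcave",
                               L = 80, constants = list()) {
  theta_p <- 135 * pi / 180  # upstream shoulder contact point
  out <- make_cell_outline(shape, model_constants()$nv)
  hh <- attr(out, "half_height")
  cz <- 11 - mac_radius
  cx <- L / 2
  # resting gap just outside the steric shell and inside the bond-formation
  # cutoff, so the quiescent bonding phase is gentle
  pr <- mac_radius + hh + 0.4
  placement <- data.frame(x = cx + pr * cos(theta_p),
                          z = cz + pr * sin(theta_p),
                          angle = theta_p - pi / 2)
  simulation_config(
    n_cells = 1, shape = shape, hct = NULL, condition = condition,
    adhesion = adhesion,
    aggregation = aggregation_params(enabled = FALSE),
    macrophages = data.frame(x = cx, radius = mac_radius), h = 20, L = L,
    velocity = velocity, seed = seed, placement = placement,
    constants = constants)
}

# Detect sustained detachment in a single-cell ramp trajectory: zero live
# bonds for `sustain` seconds AND centroid moved more than one cell
# diameter downstream of where the bonds were lost.
detect_detachment <- function(traj, sustain = 0.1, diameter = 7.82,
                              after = 0) {
  nb <- traj$nb[, 1]
  t <- traj$t_sim
  dt_rec <- stats::median(diff(t))
  need <- ceiling(sustain / dt_rec)
  run <- 0L
  for (k in seq_along(nb)) {
    if (t[k] <= after) next
    if (nb[k] == 0L) run <- run + 1L else run <- 0L
    if (run >= need) {
      k0 <- k - run + 1L  # first bond-free snapshot
      moved <- traj$comx[k, 1] - traj$comx[k0, 1]
      if (moved > diameter) return(t[k0])
      # otherwise keep scanning: still waiting for the transport condition
    }
  }
  NA_real_
}

#' Critical-detachment-velocity assay
#'
#' A single cell is equilibrated on a macrophage cap at a low flow
#' velocity, then the flow is ramped through increasing velocity levels;
#' the critical detachment velocity is the smallest level at which the cell
#' loses all bonds for a sustained window and is carried away. A cell that
#' survives the whole ramp is reported as right-censored at the maximum
#' tested velocity.
#'
#' @param preset adhesion preset name (`"normal"`, `"normoxia"`,
#'   `"hypoxia"`) or an [adhesion_params()].
#' @param condition membrane condition; inferred from the preset name when
#'   omitted.
#' @param v_levels increasing ramp levels, um/s at cap-apex height.
#' @param settle_v,settle_t equilibration velocity and duration.
#' @param hold_t hold time per ramp level, s.
#' @param seeds replicate seeds.
#' @param ... forwarded to the single-cell configuration.
#' @return list with per-seed `critical` velocities, `censored` flags,
#'   the robust `median` summary, `mean`, `sd`, and `vmax`.
#' @export
detachment_assay <- function(preset = "normal", condition = NULL,
                             v_levels = c(200, 300, 400, 500, 650, 800,
                                          1000, 1250, 1550, 1900, 2300,
                                          2800),
                             settle_v = 50, settle_t = 1.0, hold_t = 0.4,
                             seeds = 1:3, ...) {
  if (is.character(preset)) {
    if (is.null(condition)) condition <- condition_for_preset(preset)
    adhesion <- adhesion_preset(preset)
  } else {
    adhesion <- preset
    if (is.null(condition)) condition <- "sickle_normoxia"
  }
  v_levels <- sort(v_levels)
  # quiescent bonding phase, then gentle flow, then the ramp levels
  times <- c(0, 0.3, 0.3 + settle_t + hold_t * (seq_along(v_levels) - 1))
  sched <- data.frame(time = times, v = c(0, settle_v, v_levels))
  crit <- numeric(0)
  cens <- logical(0)
  for (s in seeds) {
    # run level-by-level and stop at the first sustained detachment (the
    # post-rupture flight is not of interest and is skipped)
    cfg <- single_cell_config(condition, adhesion, sched, seed = s, ...)
    st <- initialize_state(cfg)
    st <- run_sim(st, 0.3 + settle_t, record_dt = 0)$state
    found <- NA_real_
    for (lv in v_levels) {
      out <- run_sim(st, hold_t, record_dt = 0.01)
      st <- out$state
      td <- detect_detachment(out$trajectory, after = 0)
      if (!is.na(td)) {
        found <- lv
        break
      }
    }
    if (is.na(found)) {
      crit <- c(crit, max(v_levels))
      cens <- c(cens, TRUE)
    } else {
      crit <- c(crit, found)
      cens <- c(cens, FALSE)
    }
  }
  # the replicate median is the headline summary: the ramp is a discrete
  # grid and soft cells occasionally park in a metastable apex-locked state,
  # so the median is robust where the mean is not
  list(critical = crit, censored = cens, mean = mean(crit),
       median = stats::median(crit),
       sd = stats::sd(crit), vmax = max(v_levels), seeds = seeds,
       any_censored = any(cens), all_censored = all(cens))
}

#' Retention assay
#'
#' A suspension at the stated hematocrit and velocity flows past
#' wall-adhered macrophage caps; the retained count is recorded over time
#' and summarised by its plateau, over replicate seeds.
#'
#' @param preset adhesion preset name or [adhesion_params()].
#' @param condition membrane condition (inferred from preset name if NULL).
#' @param v flow velocity at cap-apex height, um/s.
#' @param hct hematocrit (area fraction).
#' @param n_cells cells in the periodic channel.
#' @param n_macs macrophage caps.
#' @param duration run length, s.
#' @param seeds replicate seeds.
#' @param aggregation NULL for the condition default, or
#'   [aggregation_params()].
#' @param shape morphology (scalar or per-cell vector).
#' @param criterion a [retention_criterion()].
#' @param mac_radius cap radius, um.
#' @param record_dt snapshot interval, s.
#' @param constants [model_constants()] overrides.
#' @return an `assay_result` list: per-seed series, plateau counts,
#'   per-macrophage means, trajectories.
#' @export
retention_assay <- function(preset = "hypoxia", condition = NULL, v = 150,
                            hct = 0.02, n_cells = 12, n_macs = 2,
                            duration = 15, seeds = 1:5, aggregation = NULL,
                            shape = "biconcave",
                            criterion = retention_criterion(),
                            mac_radius = 9, record_dt = 0.01,
                            constants = list()) {
  if (is.character(preset)) {
    if (is.null(condition)) condition <- condition_for_preset(preset)
    adhesion <- adhesion_preset(preset)
  } else {
    adhesion <- preset
    if (is.null(condition)) condition <- "sickle_hypoxia"
  }
  series <- list(); plateau <- numeric(0); reached <- logical(0)
  trajs <- list(); hash <- NULL
  for (s in seeds) {
    cfg <- simulation_config(
      n_cells = n_cells, shape = shape, hct = hct, condition = condition,
      adhesion = adhesion, aggregation = aggregation, n_macs = n_macs,
      mac_radius = mac_radius, velocity = v, seed = s,
      constants = constants)
    st <- initialize_state(cfg)
    run <- run_sim(st, duration, record_dt = record_dt)
    ser <- count_retained(run$trajectory, criterion)
    pl <- plateau_info(ser)
    series[[length(series) + 1]] <- ser
    plateau <- c(plateau, pl$value)
    reached <- c(reached, pl$reached)
    trajs[[length(trajs) + 1]] <- run$trajectory
    hash <- run$trajectory$config_hash
  }
  structure(list(
    name = "retention", series = series, plateau = plateau,
    per_mac = plateau / n_macs, reached = reached, seeds = seeds,
    criterion = criterion, config_hash = hash, n_macs = n_macs,
    trajectories = trajs,
    mean = mean(plateau), sd = stats::sd(plateau),
    per_mac_mean = mean(plateau) / n_macs),
    class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf("%s assay: %d replicates\n", x$name, length(x$seeds)))
  cat(sprintf("  plateau retained: mean %.2f (sd %.2f); per macrophage %.2f\n",
              x$mean, x$sd, x$per_mac_mean))
  if (!all(x$reached)) cat("  note: plateau not reached in all replicates\n")
  invisible(x)
}

# Classify capture events as cluster filtration (>= 2 cells of the same
# aggregate captured within `window` seconds) or transitive filtration.
classify_filtration <- function(traj, criterion = retention_criterion(),
                                window = 0.5) {
  ser <- count_retained(traj, criterion)
  ret <- attr(ser, "retained_matrix")
  nc <- ncol(ret)
  first_idx <- rep(NA_integer_, nc)
  for (c in seq_len(nc)) {
    w <- which(ret[, c])
    if (length(w) > 0) first_idx[c] <- w[1]
  }
  captured <- which(!is.na(first_idx))
  if (length(captured) == 0)
    return(data.frame(cell = integer(0), time = numeric(0),
                      mechanism = character(0)))
  out <- data.frame(cell = captured,
                    time = traj$t_sim[first_idx[captured]],
                    mechanism = "transitive", stringsAsFactors = FALSE)
  for (i in seq_along(captured)) {
    c <- captured[i]
    k <- first_idx[c]
    kb <- max(1L, k - 1L)
    mates <- which(traj$cluster[kb, ] == traj$cluster[kb, c])
    mates <- setdiff(mates, c)
    if (length(mates) > 0) {
      mt <- first_idx[mates]
      if (any(!is.na(mt) &
              abs(traj$t_sim[mt] - traj$t_sim[k]) <= window))
        out$mechanism[i] <- "cluster"
    }
  }
  out
}

#' Aggregation assay (paired)
#'
#' Paired hypoxia retention runs differing only in the Morse aggregation
#' flag (identical seeds), with classification of each capture as cluster
#' or transitive filtration.
#'
#' @param seeds replicate seeds.
#' @param De Morse well depth for the aggregation-on arm.
#' @param ... forwarded to [retention_assay()].
#' @return list with `on`, `off` assay results, `ratio` of plateau means,
#'   and per-arm event classifications.
#' @export
aggregation_assay <- function(seeds = 1:5, De = aggregation_params()$De,
                              ...) {
  on <- retention_assay(preset = "hypoxia", seeds = seeds,
                        aggregation = aggregation_params(De = De,
                                                         enabled = TRUE),
                        ...)
  off <- retention_assay(preset = "hypoxia", seeds = seeds,
                         aggregation = aggregation_params(enabled = FALSE),
                         ...)
  ev_on <- lapply(on$trajectories, classify_filtration)
  ev_off <- lapply(off$trajectories, classify_filtration)
  list(on = on, off = off,
       ratio = on$mean / max(off$mean, 1e-9),
       events_on = ev_on, events_off = ev_off,
       cluster_on = sum(vapply(ev_on, function(e)
         sum(e$mechanism == "cluster"), 1)),
       cluster_off = sum(vapply(ev_off, function(e)
         sum(e$mechanism == "cluster"), 1)))
}

#' Hematocrit sweep
#'
#' Retention runs at several hematocrits; the hematocrit is varied by
#' changing the channel length while the cell count stays constant. Higher
#' hematocrit reaches the plateau faster.
#'
#' @param levels hematocrit levels (area fractions).
#' @param seeds replicate seeds.
#' @param ... forwarded to [retention_assay()].
#' @return list of assay results plus a `time_to_plateau` matrix
#'   (level x seed).
#' @export
hct_sweep <- function(levels = c(0.015, 0.028, 0.036, 0.05), seeds = 1:3,
                      ...) {
  res <- lapply(levels, function(hc)
    retention_assay(preset = "hypoxia", hct = hc, n_macs = 1,
                    seeds = seeds, ...))
  ttp <- t(vapply(res, function(r)
    vapply(r$series, function(s) plateau_info(s)$time_to_plateau,
           numeric(1)), numeric(length(seeds))))
  names(res) <- paste0("hct_", levels)
  list(results = res, levels = levels, time_to_plateau = ttp)
}

#' Constant-velocity retention sweep
#'
#' Retention plateau versus flow velocity. Plateau counts are statistically
#' flat across the red-pulp-like range and decrease at higher velocities.
#'
#' @param velocities velocities at cap-apex height, um/s.
#' @param seeds replicate seeds.
#' @param hct hematocrit.
#' @param ... forwarded to [retention_assay()].
#' @return list of assay results indexed by velocity.
#' @export
velocity_assay <- function(velocities = c(100, 200, 300, 400, 500),
                           seeds = 1:3, hct = 0.015, ...) {
  res <- lapply(velocities, function(v)
    retention_assay(preset = "hypoxia", v = v, hct = hct, n_macs = 1,
                    seeds = seeds, ...))
  names(res) <- paste0("v_", velocities)
  list(results = res, velocities = velocities,
       plateau_mean = vapply(res, function(r) r$mean, 1),
       plateau_sd = vapply(res, function(r) r$sd, 1))
}

#' Step-wise decreasing velocity assay
#'
#' The flow is decreased step-wise (by default 1000 -> 100 um/s); the assay
#' reports the velocity step at which the first capture occurs.
#'
#' @param v_steps decreasing velocity levels, um/s.
#' @param hold_t hold time per level, s.
#' @param seeds replicate seeds.
#' @param n_cells,hct suspension.
#' @param ... forwarded to [simulation_config()].
#' @return list with per-seed first-capture velocity and time.
#' @export
stepwise_velocity_assay <- function(v_steps = c(1000, 750, 500, 250, 100),
                                    hold_t = 3, seeds = 1:3, n_cells = 8,
                                    hct = 0.015, ...) {
  sched <- data.frame(time = hold_t * (seq_along(v_steps) - 1), v = v_steps)
  first_v <- numeric(0); first_t <- numeric(0)
  for (s in seeds) {
    cfg <- simulation_config(n_cells = n_cells, hct = hct,
                             condition = "sickle_hypoxia", n_macs = 1,
                             velocity = sched, seed = s, ...)
    st <- initialize_state(cfg)
    run <- run_sim(st, hold_t * length(v_steps), record_dt = 0.01)
    ser <- count_retained(run$trajectory)
    k <- which(ser$retained > 0)[1]
    if (is.na(k)) {
      first_v <- c(first_v, NA_real_); first_t <- c(first_t, NA_real_)
    } else {
      t0 <- run$trajectory$t_sim[k]
      first_v <- c(first_v, sched$v[findInterval(t0, sched$time)])
      first_t <- c(first_t, t0)
    }
  }
  list(first_capture_v = first_v, first_capture_t = first_t,
       schedule = sched, seeds = seeds)
}

#' Single-cell flyby assay
#'
#' Releases one cell upstream of a cap at the standard release offset and
#' records, per velocity, whether the membrane comes within the bond
#' formation cutoff d_on of the cap surface ("contact"). Faster flow
#' deflects the cell over the cap (deformability lift grows with shear
#' rate) and prevents contact.
#'
#' @param velocities velocity grid, um/s at cap-apex height.
#' @param seeds replicate seeds.
#' @param clearance release clearance between cell underside and cap apex,
#'   um (default 0.3: within d_on at rest).
#' @param condition membrane condition.
#' @param mac_radius cap radius.
#' @return list with the contact matrix (velocity x seed), per-velocity
#'   contact fraction, and the largest velocity with majority contact.
#' @export
flyby_assay <- function(velocities = c(150, 250, 500, 750, 1000),
                        seeds = 1:3, clearance = 0.3,
                        condition = "sickle_hypoxia", mac_radius = 9) {
  out <- make_cell_outline("biconcave", model_constants()$nv)
  hh <- attr(out, "half_height")
  L <- 90
  contact <- matrix(FALSE, length(velocities), length(seeds))
  for (iv in seq_along(velocities)) {
    v <- velocities[iv]
    for (is in seq_along(seeds)) {
      placement <- data.frame(x = L / 2 - 30, z = 11 + clearance + hh,
                              angle = 0)
      cfg <- simulation_config(
        n_cells = 1, hct = NULL, condition = condition,
        macrophages = data.frame(x = L / 2, radius = mac_radius), L = L,
        velocity = v, seed = seeds[is], placement = placement,
        aggregation = aggregation_params(enabled = FALSE))
      st <- initialize_state(cfg)
      u0 <- couette_profile(placement$z, v_to_Utop(v, cfg), cfg$h)
      duration <- 70 / u0 + 0.2
      run <- run_sim(st, duration, record_dt = 0.01)
      contact[iv, is] <- min(run$trajectory$gapmin[, 1]) < cfg$adhesion$d_on
    }
  }
  frac <- rowMeans(contact)
  idx <- which(frac >= 0.5)
  list(velocities = velocities, contact = contact, contact_fraction = frac,
       threshold = if (length(idx) > 0) max(velocities[idx]) else NA_real_)
}

#' Shape panel
#'
#' Retention under hypoxia for suspensions of each morphology (and an
#' equal-proportion mix), with identical seeds across panels; reports
#' plateau counts and the resulting adhesion-likelihood ranking.
#'
#' @param shapes panel members.
#' @param seeds replicate seeds.
#' @param n_cells cells per run.
#' @param ... forwarded to [retention_assay()].
#' @return list with per-shape results, mean plateau counts, and the
#'   ranking (decreasing retention).
#' @export
shape_panel <- function(shapes = c("biconcave", "elongated", "granular",
                                   "sickle", "mix"),
                        seeds = 1:5, n_cells = 12, hct = 0.02, ...) {
  res <- list()
  for (sh in shapes) {
    shp <- if (sh == "mix")
      rep_len(c("biconcave", "elongated", "granular", "sickle"), n_cells)
    else sh
    res[[sh]] <- retention_assay(preset = "hypoxia", shape = shp,
                                 n_cells = n_cells, hct = hct,
                                 seeds = seeds, ...)
  }
  means <- vapply(res, function(r) r$mean, 1)
  per_seed <- vapply(res, function(r) r$plateau, numeric(length(seeds)))
  list(results = res, mean_plateau = means,
       per_seed = per_seed,
       ranking = names(sort(means, decreasing = TRUE)))
}

#' Fit the adhesion strength to observed detachment velocities
#'
#' Bisection search for the adhesion strength Ks whose simulated critical
#' detachment velocity matches an observed target, holding the kinetic
#' rates fixed; the search range is the documented literature range.
#' Optionally emits the local sensitivity table of the critical velocity to
#' (Ks, kon0, koff0).
#'
#' @param target_v observed critical detachment velocity, um/s.
#' @param kon0,koff0 kinetic rates held fixed during the fit.
#' @param condition membrane condition for the virtual cell.
#' @param Ks_range search interval, uN/m.
#' @param seeds seeds per evaluation.
#' @param n_iter bisection iterations.
#' @param sensitivity also compute the sensitivity table.
#' @param ... forwarded to [detachment_assay()].
#' @return list with `Ks`, fitted [adhesion_params()], the bisection
#'   `trace`, the achieved velocity and residual, and optionally
#'   `sensitivity`.
#' @export
calibrate_adhesion <- function(target_v, kon0 = 5.42e4, koff0 = 2.71,
                               condition = "sickle_normoxia",
                               Ks_range = c(1, 10), seeds = 1:2,
                               n_iter = 7, sensitivity = FALSE, ...) {
  eval_v <- function(Ks) {
    p <- adhesion_params(Ks = Ks, kon0 = kon0, koff0 = koff0)
    detachment_assay(p, condition = condition, seeds = seeds, ...)$median
  }
  lo <- Ks_range[1]; hi <- Ks_range[2]
  v_lo <- eval_v(lo); v_hi <- eval_v(hi)
  trace <- data.frame(Ks = c(lo, hi), v = c(v_lo, v_hi))
  if (target_v <= v_lo) {
    best <- lo
  } else if (target_v >= v_hi) {
    best <- hi
  } else {
    for (it in seq_len(n_iter)) {
      mid <- sqrt(lo * hi)
      v_mid <- eval_v(mid)
      trace <- rbind(trace, data.frame(Ks = mid, v = v_mid))
      if (v_mid < target_v) lo <- mid else hi <- mid
    }
    best <- sqrt(lo * hi)
  }
  achieved <- eval_v(best)
  out <- list(Ks = best,
              params = adhesion_params(Ks = best, kon0 = kon0,
                                       koff0 = koff0),
              achieved_v = achieved, target_v = target_v,
              residual = achieved - target_v, trace = trace)
  if (sensitivity)
    out$sensitivity <- sensitivity_table(Ks = best, kon0 = kon0,
                                         koff0 = koff0,
                                         condition = condition,
                                         seeds = seeds, ...)
  out
}

#' Sensitivity of the critical detachment velocity
#'
#' Normalised one-sided sensitivities |d ln v_c / d ln p| of the critical
#' detachment velocity to Ks, kon0 and koff0 (each scaled by `factor` in
#' turn), reported with the implied importance ranking.
#'
#' @param Ks,kon0,koff0 baseline parameter values.
#' @param factor multiplicative perturbation.
#' @param condition membrane condition.
#' @param seeds seeds per evaluation.
#' @param ... forwarded to [detachment_assay()].
#' @return data.frame `parameter`, `sensitivity`, plus attribute
#'   `"ranking"`.
#' @export
sensitivity_table <- function(Ks = 2.9, kon0 = 5.42e4, koff0 = 2.71,
                              factor = 1.6, condition = "sickle_normoxia",
                              seeds = 1:2, ...) {
  eval_v <- function(Ks_, kon_, koff_) {
    p <- adhesion_params(Ks = Ks_, kon0 = kon_, koff0 = koff_)
    detachment_assay(p, condition = condition, seeds = seeds, ...)$median
  }
  v0 <- eval_v(Ks, kon0, koff0)
  s_Ks <- abs(log(eval_v(Ks * factor, kon0, koff0) / v0)) / log(factor)
  s_kon <- abs(log(eval_v(Ks, kon0 * factor, koff0) / v0)) / log(factor)
  s_koff <- abs(log(eval_v(Ks, kon0, koff0 / factor) / v0)) / log(factor)
  out <- data.frame(parameter = c("Ks", "kon0", "koff0"),
                    sensitivity = c(s_Ks, s_kon, s_koff))
  attr(out, "ranking") <-
    out$parameter[order(out$sensitivity, decreasing = TRUE)]
  out
}
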