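# Shared in-code fixtures: synthetic trajectories and small meshes.

# Minimal trajectory object with hand-specified channels, for counting and
# statistics tests. nb: nsnap x ncell integer matrix.
toy_trajectory <- function(t, nb, speed, comx = NULL, comz = NULL,
                           cluster = NULL, v_bulk = 150) {
  nsnap <- length(t)
  ncell <- ncol(nb)
  if (is.null(comx)) comx <- matrix(seq_len(nsnap), nsnap, ncell)
  if (is.null(comz)) comz <- matrix(10, nsnap, ncell)
  if (is.null(cluster)) cluster <- matrix(seq_len(ncell), nsnap, ncell,
                                          byrow = TRUE)
  structure(list(
    t = t, t_sim = t, comx = comx, comz = comz, speed = speed, nb = nb,
    gapmin = matrix(Inf, nsnap, ncell), cluster = cluster,
    macs = matrix(c(30, 2, 9), 1, 3), h = 20, L = 60,
    schedule = data.frame(time = 0, v = v_bulk), apex = 11,
    condition = "sickle_hypoxia", time_scaling = 1, d_on = 0.75,
    config_hash = "deadbeef"),
    class = "splenosim_trajectory")
}

# Two-cell quiescent configuration with controllable aggregation.
doublet_config <- function(De, enabled = TRUE, seed = 1, gap = 0.35) {
  out <- make_cell_outline("biconcave", model_constants()$nv)
  hh <- attr(out, "half_height")
  simulation_config(
    n_cells = 2, hct = NULL, L = 40, n_macs = 0,
    condition = "sickle_hypoxia",
    aggregation = aggregation_params(De = De, enabled = enabled),
    velocity = 0, seed = seed,
    placement = data.frame(x = c(20, 20), z = c(8, 8 + 2 * hh + gap),
                           angle = c(0, 0)))
}
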