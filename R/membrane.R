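# Elastic membrane model for triangulated RBC surfaces: wormlike-chain +
# power-law springs on edges, dihedral-angle bending, local/global area and
# global volume penalties. Mesh-level spring constants are mapped from the
# macroscopic shear modulus through the analytic hexagonal-network relation
# and verified by the stretch test.

#' Membrane parameter set
#'
#' Macroscopic moduli plus spring/constraint parameters. `E_s` is the
#' membrane shear modulus in uN/m (healthy reference E_s0 = 4.792 uN/m) and
#' `E_b` the bending modulus in J (reference E_b0 = 2.9e-19 J).
#'
#' @param E_s shear modulus, uN/m.
#' @param E_b bending modulus, J.
#' @param x0 resting-to-maximum spring extension ratio of the WLC springs.
#' @param k_area_local per-triangle area stiffness, pN/um.
#' @param k_area_global global area stiffness, pN/um.
#' @param k_volume global volume stiffness, pN/um^2.
#' @param kBT thermal energy, pN um.
#' @return a `membrane_params` list.
#' @export
membrane_params <- function(E_s = 4.792, E_b = 2.9e-19, x0 = 1 / 2.2,
                            k_area_local = 200, k_area_global = 3000,
                            k_volume = 3000, kBT = .kBT) {
  stopifnot(E_s > 0, E_b > 0, x0 > 0, x0 < 1,
            k_area_local >= 0, k_area_global >= 0, k_volume >= 0)
  structure(list(E_s = E_s, E_b = E_b, x0 = x0,
                 k_area_local = k_area_local,
                 k_area_global = k_area_global, k_volume = k_volume,
                 kBT = kBT),
            class = "membrane_params")
}

#' Oxygenation-dependent moduli
#'
#' Sickle RBCs stiffen with deoxygenation: normoxia multiplies both moduli
#' of the healthy reference by 5, hypoxia by 50; a normal (healthy) cell is
#' unchanged.
#'
#' @param condition `"normoxia"` or `"hypoxia"`.
#' @param base a [membrane_params()] with the healthy reference moduli.
#' @param cell_type `"sickle"` or `"normal"`.
#' @return a [membrane_params()] with scaled `E_s`, `E_b`.
#' @export
condition_params <- function(condition = c("normoxia", "hypoxia"),
                             base = membrane_params(),
                             cell_type = c("sickle", "normal")) {
  condition <- match.arg(condition)
  cell_type <- match.arg(cell_type)
  if (cell_type == "normal") return(base)
  mult <- switch(condition, normoxia = 5, hypoxia = 50)
  out <- base
  out$E_s <- base$E_s * mult
  out$E_b <- base$E_b * mult
  out
}

# Persistence length from the shear modulus via the hexagonal-network
# relation for WLC + POW (m = 2) springs at resting extension x0:
#   mu0 = (sqrt(3) kT / (4 p l0)) [ x0/(2(1-x0)^3) - 1/(4(1-x0)^2) + 1/4 ]
#         + (3 sqrt(3) / (4 l0)) f_wlc(l0)
# with kp fixed by the zero-tension condition kp = l0^2 f_wlc(l0).
wlc_persistence <- function(E_s_pN_um, l0, x0, kBT) {
  c1 <- x0 / (2 * (1 - x0)^3) - 1 / (4 * (1 - x0)^2) + 0.25
  c2 <- 0.25 / (1 - x0)^2 - 0.25 + x0
  # mu0 = sqrt(3) kT c1 / (4 p l0) + 3 sqrt(3) (kT/p) c2 / (4 l0)
  #     = (kT / (p l0)) * (sqrt(3)/4) * (c1 + 3 c2)
  kBT * (sqrt(3) / 4) * (c1 + 3 * c2) / (E_s_pN_um * l0)
}

#' Membrane reference state
#'
#' Captures the stress-free reference of a mesh: per-edge rest lengths and
#' spring constants, per-dihedral spontaneous angles, per-triangle reference
#' areas, and the global reference area/volume. The reference is fixed at
#' initialisation.
#'
#' @param mesh a [tri_mesh()].
#' @param params a [membrane_params()].
#' @return a `membrane_state` list (topology + reference + parameters ready
#'   for the force kernel).
#' @export
membrane_state <- function(mesh, params = membrane_params()) {
  v <- mesh$vertices
  tr <- mesh$triangles
  ed <- mesh$edges
  # dihedral table: edge (a, b) with opposite c in triangle (a, b, c) and d
  # in triangle (b, a, d)
  he_key <- c(paste(tr[, 1], tr[, 2]), paste(tr[, 2], tr[, 3]),
              paste(tr[, 3], tr[, 1]))
  he_opp <- c(tr[, 3], tr[, 1], tr[, 2])
  opp <- setNames(he_opp, he_key)
  cvert <- opp[paste(ed[, 1], ed[, 2])]
  dvert <- opp[paste(ed[, 2], ed[, 1])]
  if (anyNA(cvert) || anyNA(dvert)) stop("open mesh: dihedral incomplete")
  dihed <- cbind(ed[, 1], ed[, 2], as.integer(cvert), as.integer(dvert))
  el <- sqrt(rowSums((v[ed[, 1], , drop = FALSE] -
                      v[ed[, 2], , drop = FALSE])^2))
  l0_mean <- mean(el)
  p_len <- wlc_persistence(params$E_s, l0_mean, params$x0, params$kBT)
  kT_over_p <- params$kBT / p_len
  Lmax <- el / params$x0
  c2 <- 0.25 / (1 - params$x0)^2 - 0.25 + params$x0
  kp <- el^2 * kT_over_p * c2
  # spontaneous dihedral angles of the reference shape
  theta0 <- dihedral_angles(v, dihed)
  At0 <- triangle_areas(v, tr)
  av <- mesh_area_volume(mesh)
  k_bend <- 2 * params$E_b * 1e18 / sqrt(3)  # pN um
  structure(list(
    mesh = mesh, params = params,
    edges_0 = ed - 1L, tris_0 = tr - 1L, dihed_0 = dihed - 1L,
    kernel_params = list(
      kT_over_p = kT_over_p, k_bend = k_bend,
      k_area_local = params$k_area_local,
      k_area_global = params$k_area_global, k_volume = params$k_volume,
      Lmax = Lmax, kp = kp, theta0 = theta0, At0 = At0,
      A0 = unname(av["area"]), V0 = unname(av["volume"])),
    reference = list(edge_lengths = el, area = unname(av["area"]),
                     volume = unname(av["volume"]), At0 = At0,
                     persistence = p_len)),
    class = "membrane_state")
}

# Signed dihedral angles for an n x 4 (a, b, c, d) table.
dihedral_angles <- function(v, dihed) {
  a <- v[dihed[, 1], , drop = FALSE]
  b <- v[dihed[, 2], , drop = FALSE]
  cc <- v[dihed[, 3], , drop = FALSE]
  d <- v[dihed[, 4], , drop = FALSE]
  e <- b - a
  cr <- function(u, w) cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                             u[, 3] * w[, 1] - u[, 1] * w[, 3],
                             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  n1 <- cr(b - a, cc - a)
  n2 <- cr(a - b, d - b)
  le <- sqrt(rowSums(e^2))
  inv <- 1 / sqrt(rowSums(n1^2) * rowSums(n2^2))
  cth <- rowSums(n1 * n2) * inv
  sth <- rowSums(cr(n1, n2) * e) * inv / le
  atan2(sth, cth)
}

#' Membrane forces
#'
#' Elastic force on every vertex for a (possibly deformed) vertex
#' configuration, as the exact negative gradient of the membrane energy
#' (springs + bending + local/global area + volume). Internal forces only:
#' they sum to zero and carry zero net torque.
#'
#' @param state a [membrane_state()].
#' @param positions optional n x 3 matrix of current vertex positions
#'   (defaults to the reference mesh vertices).
#' @return list with `forces` (n x 3, pN), `energy` (pN um), `area`,
#'   `volume`, and the energy `parts`.
#' @export
membrane_forces <- function(state, positions = NULL) {
  stopifnot(inherits(state, "membrane_state"))
  if (is.null(positions)) positions <- state$mesh$vertices
  membrane3d_forces(positions, state$edges_0, state$tris_0, state$dihed_0,
                    state$kernel_params)
}

#' Axial stretch test
#'
#' Standard calibration harness: opposite axial loads are distributed over
#' the outermost 2% of vertices at each x-extreme of a biconcave mesh, the
#' shape is relaxed quasi-statically at each load, and the axial/transverse
#' diameters are recorded. Used to verify that mesh-level spring constants
#' reproduce the intended macroscopic shear modulus.
#'
#' @param mesh a biconcave [tri_mesh()].
#' @param params a [membrane_params()].
#' @param forces vector of total stretching forces, pN.
#' @param n_relax relaxation iterations per load step.
#' @param dt_over_zeta overdamped step size.
#' @return data.frame with columns `force`, `axial`, `transverse`.
#' @export
stretch_test <- function(mesh, params = membrane_params(),
                         forces = seq(0, 40, by = 10), n_relax = 1500,
                         dt_over_zeta = 2e-4) {
  state <- membrane_state(mesh, params)
  v <- mesh$vertices
  n <- nrow(v)
  ntag <- max(3L, ceiling(0.02 * n))
  right <- order(v[, 1], decreasing = TRUE)[seq_len(ntag)]
  left <- order(v[, 1])[seq_len(ntag)]
  x <- v
  out <- data.frame(force = numeric(0), axial = numeric(0),
                    transverse = numeric(0))
  for (f in sort(forces)) {
    fext <- matrix(0, n, 3)
    fext[right, 1] <- f / ntag
    fext[left, 1] <- -f / ntag
    x <- membrane3d_relax(x, state$edges_0, state$tris_0, state$dihed_0,
                          state$kernel_params, fext, as.integer(n_relax),
                          dt_over_zeta)
    out <- rbind(out, data.frame(force = f,
                                 axial = diff(range(x[, 1])),
                                 transverse = diff(range(x[, 2]))))
  }
  out
}
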