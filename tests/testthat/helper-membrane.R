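# Effective shear modulus of a flat hexagonal spring patch under affine
# simple shear, probed through the membrane energy kernel; the analytic
# small-strain energy density gives mu = d2E/dgamma2 / Area.
patch_shear_modulus <- function(E_s, l0 = 0.55, n = 16, gam = 1e-3) {
  pts <- NULL
  for (i in 0:n) for (j in 0:n)
    pts <- rbind(pts, c((j + 0.5 * (i %% 2)) * l0, i * l0 * sqrt(3) / 2, 0))
  idx <- function(i, j) i * (n + 1) + j + 1
  tris <- NULL
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    if (i %% 2 == 0) {
      tris <- rbind(tris, c(idx(i, j), idx(i, j + 1), idx(i + 1, j)),
                    c(idx(i, j + 1), idx(i + 1, j + 1), idx(i + 1, j)))
    } else {
      tris <- rbind(tris, c(idx(i, j), idx(i, j + 1), idx(i + 1, j + 1)),
                    c(idx(i, j), idx(i + 1, j + 1), idx(i + 1, j)))
    }
  }
  he <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  ed <- unique(cbind(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2])))
  el <- sqrt(rowSums((pts[ed[, 1], ] - pts[ed[, 2], ])^2))
  params <- membrane_params(E_s = E_s)
  x0 <- params$x0
  p_len <- splenosim:::wlc_persistence(E_s, mean(el), x0, params$kBT)
  c2 <- 0.25 / (1 - x0)^2 - 0.25 + x0
  kp <- el^2 * (params$kBT / p_len) * c2
  kpar <- list(kT_over_p = params$kBT / p_len, k_bend = 0,
               k_area_local = 0, k_area_global = 0, k_volume = 0,
               Lmax = el / x0, kp = kp, theta0 = numeric(0),
               At0 = rep(1, nrow(tris)), A0 = 1, V0 = 0)
  dih <- matrix(0L, 0, 4)
  en <- function(g) {
    xx <- pts
    xx[, 1] <- xx[, 1] + g * xx[, 2]
    splenosim:::membrane3d_forces(xx, ed - 1L, tris - 1L, dih, kpar)$energy
  }
  A <- n * n * l0^2 * sqrt(3) / 2
  (en(gam) + en(-gam) - 2 * en(0)) / (gam^2) / A
}
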