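# Mesh synthesis for RBCs (four morphologies) and wall-adhered macrophage
# caps, with exact surface-area/volume targeting, plus mesh validation and
# text-format I/O (OFF, legacy VTK polydata).

#' Triangulated cell surface
#'
#' Light container for a closed, outward-oriented triangulated surface.
#' Vertices are in micrometres. Triangles are 1-based vertex index triples.
#'
#' @param vertices numeric matrix (n x 3).
#' @param triangles integer matrix (m x 3), outward (CCW seen from outside).
#' @param validate check manifoldness, orientation and Euler characteristic.
#' @return an object of class `tri_mesh` with elements `vertices`,
#'   `triangles` and derived `edges`.
#' @export
tri_mesh <- function(vertices, triangles, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(triangles) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(triangles) == 3)
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         edges = mesh_edges(triangles)),
                    class = "tri_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.tri_mesh <- function(x, ...) {
  av <- mesh_area_volume(x)
  cat(sprintf("tri_mesh: %d vertices, %d triangles, %d edges\n",
              nrow(x$vertices), nrow(x$triangles), nrow(x$edges)))
  cat(sprintf("  area %.4f um^2, volume %.4f um^3\n", av[1], av[2]))
  invisible(x)
}

# Unique undirected edges from a triangle index matrix.
mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Validate a triangulated surface
#'
#' Checks that the mesh is a closed orientable 2-manifold of genus 0
#' (every directed edge used exactly once, Euler characteristic 2), that all
#' triangles are non-degenerate, and that orientation is outward (positive
#' enclosed volume).
#'
#' @param mesh a [tri_mesh()].
#' @return invisibly `TRUE`; otherwise an error describing the defect.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  nV <- nrow(v); nF <- nrow(tr)
  if (any(tr < 1L) || any(tr > nV)) stop("triangle indices out of range")
  # each directed half-edge must appear exactly once (closed + orientable)
  he <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key))
    stop("mesh is not a consistently oriented manifold: duplicated half-edge")
  rkey <- paste(he[, 2], he[, 1])
  if (!all(rkey %in% key))
    stop("mesh is not closed: boundary half-edge found")
  nE <- nrow(mesh$edges)
  if (nV - nE + nF != 2L)
    stop(sprintf("Euler characteristic V-E+F = %d, expected 2 (genus 0)",
                 nV - nE + nF))
  a <- triangle_areas(v, tr)
  if (any(a <= 1e-12)) stop("degenerate (zero-area) triangle present")
  av <- mesh_area_volume(mesh)
  if (av[2] <= 0)
    stop("negative enclosed volume: triangle normals are not outward")
  invisible(TRUE)
}

triangle_areas <- function(v, tr) {
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Surface area and enclosed volume of a closed mesh
#'
#' Area is the sum of triangle areas; volume uses the divergence theorem
#' (sum of signed tetrahedra spanned from the origin), positive for outward
#' orientation.
#'
#' @param mesh a [tri_mesh()] or a list with `vertices` and `triangles`.
#' @return named numeric vector `c(area =, volume =)` in um^2 / um^3.
#' @export
mesh_area_volume <- function(mesh) {
  v <- mesh$vertices; tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  cc <- v[tr[, 3], , drop = FALSE]
  area <- sum(triangle_areas(v, tr))
  vol <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
             a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
             a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
  c(area = area, volume = vol)
}

#' RBC shape specification
#'
#' @param shape one of `"biconcave"`, `"elongated"`, `"granular"`, `"sickle"`.
#' @param target_area surface area in um^2 (default 132.87).
#' @param target_volume enclosed volume in um^3 (default 92.46).
#' @param n_vertices vertex count of the generated mesh (default 500).
#' @return a `cell_shape_spec` list.
#' @export
cell_shape_spec <- function(shape = c("biconcave", "elongated", "granular",
                                      "sickle"),
                            target_area = 132.87, target_volume = 92.46,
                            n_vertices = 500L) {
  shape <- match.arg(shape)
  stopifnot(target_area > 0, target_volume > 0, n_vertices >= 12)
  # isoperimetric feasibility: sphere of this volume has the least area
  s_min <- (36 * pi * target_volume^2)^(1 / 3)
  if (target_area < s_min * (1 - 1e-9))
    stop(sprintf(paste0("infeasible area/volume pair: a volume of %.2f um^3 ",
                        "requires area >= %.2f um^2 (given %.2f)"),
                 target_volume, s_min, target_area))
  structure(list(shape = shape, target_area = target_area,
                 target_volume = target_volume,
                 n_vertices = as.integer(n_vertices)),
            class = "cell_shape_spec")
}

#' Macrophage cap specification
#'
#' A wall-adhered macrophage modeled as a rigid spherical cap of the stated
#' apex height sitting on the bottom wall.
#'
#' @param radius sphere radius in um (admissible range 8 to 11 by default).
#' @param cap_height apex height h_M above the wall in um (default 11).
#' @param base_center length-2 numeric, (x, y) position on the wall.
#' @param radius_range admissible radius interval.
#' @return a `macrophage_spec` list.
#' @export
macrophage_spec <- function(radius = 11, cap_height = 11,
                            base_center = c(0, 0),
                            radius_range = c(8, 11)) {
  if (cap_height <= 0 || cap_height > 2 * radius)
    stop("infeasible cap: need 0 < cap_height <= 2 * radius")
  if (radius < radius_range[1] - 1e-9 || radius > radius_range[2] + 1e-9)
    stop(sprintf("macrophage radius %.2f outside admissible range [%g, %g]",
                 radius, radius_range[1], radius_range[2]))
  structure(list(radius = radius, cap_height = cap_height,
                 base_center = as.numeric(base_center)),
            class = "macrophage_spec")
}

# ---- sphere-topology scaffold with an exact vertex count ------------------

# Latitude-ring point layout: 2 poles + rings with counts proportional to
# sin(theta), summing exactly to n_vertices. Deterministic. Returns list of
# theta/phi per vertex plus ring bookkeeping.
sphere_rings <- function(n_vertices) {
  n_in <- n_vertices - 2L
  k <- max(3L, round(sqrt(pi * n_in) / 2))
  theta <- pi * seq_len(k) / (k + 1)
  w <- sin(theta)
  ni <- pmax(3L, round(n_in * w / sum(w)))
  # fix rounding drift on the largest rings
  while (sum(ni) != n_in) {
    j <- if (sum(ni) > n_in) which.max(ni) else which.max(w / ni)
    ni[j] <- ni[j] + if (sum(ni) > n_in) -1L else 1L
  }
  rings <- vector("list", k)
  for (i in seq_len(k)) {
    off <- 0.5 * (i %% 2)
    rings[[i]] <- list(theta = theta[i],
                       phi = 2 * pi * (seq_len(ni[i]) - 1 + off) / ni[i])
  }
  list(k = k, ni = ni, rings = rings)
}

# Zipper-triangulate between two index rings ordered by angle (each closed).
# Produces length(ia) + length(ib) triangles; `phia`/`phib` are the ring
# angles used for the merge order.
zip_rings <- function(ia, phia, ib, phib) {
  m <- length(ia); n <- length(ib)
  tris <- matrix(0L, m + n, 3)
  a <- 1L; b <- 1L; cnt <- 0L
  # advance the ring whose next angular boundary comes first
  nexta <- function(a) if (a < m) phia[a + 1] else phia[1] + 2 * pi
  nextb <- function(b) if (b < n) phib[b + 1] else phib[1] + 2 * pi
  while (a <= m || b <= n) {
    cnt <- cnt + 1L
    if (b > n || (a <= m && nexta(a) <= nextb(b))) {
      a2 <- if (a < m) a + 1L else 1L
      tris[cnt, ] <- c(ia[a2], ia[a], ib[if (b <= n) b else 1L])
      a <- a + 1L
    } else {
      b2 <- if (b < n) b + 1L else 1L
      tris[cnt, ] <- c(ib[b], ib[b2], ia[if (a <= m) a else 1L])
      b <- b + 1L
    }
  }
  tris
}

# Closed genus-0 triangulation with exactly n_vertices vertices laid out on
# the unit sphere. Returns vertices (n x 3) and triangles; for V = 500 this
# yields 996 triangles and 1494 edges (F = 2V - 4, E = 3V - 6).
unit_sphere_mesh <- function(n_vertices) {
  sr <- sphere_rings(n_vertices)
  verts <- matrix(0, n_vertices, 3)
  verts[1, ] <- c(0, 0, 1)           # north pole
  verts[2, ] <- c(0, 0, -1)          # south pole
  idx <- vector("list", sr$k)
  nxt <- 3L
  for (i in seq_len(sr$k)) {
    r <- sr$rings[[i]]
    ni <- length(r$phi)
    idx[[i]] <- nxt:(nxt + ni - 1L)
    verts[idx[[i]], ] <- cbind(sin(r$theta) * cos(r$phi),
                               sin(r$theta) * sin(r$phi),
                               rep(cos(r$theta), ni))
    nxt <- nxt + ni
  }
  tris <- list()
  # north fan (pole at +z, ring 1): outward CCW
  i1 <- idx[[1]]; n1 <- length(i1)
  tris[[1]] <- cbind(rep(1L, n1), i1, i1[c(2:n1, 1)])
  for (i in seq_len(sr$k - 1)) {
    tris[[i + 1]] <- zip_rings(idx[[i]], sr$rings[[i]]$phi,
                               idx[[i + 1]], sr$rings[[i + 1]]$phi)
  }
  ik <- idx[[sr$k]]; nk <- length(ik)
  tris[[sr$k + 1]] <- cbind(rep(2L, nk), ik[c(2:nk, 1)], ik)
  tr <- orient_outward(verts, do.call(rbind, tris))
  list(vertices = verts, triangles = tr, theta = acos(pmin(1, pmax(-1, verts[, 3]))))
}

# Flip all triangles if the enclosed signed volume is negative (the ring
# zipper is internally consistent, so a global flip restores outwardness).
orient_outward <- function(verts, tris) {
  av <- mesh_area_volume(list(vertices = verts, triangles = tris))
  if (av[2] < 0) tris[, c(2, 3)] <- tris[, c(3, 2)]
  tris
}

# ---- analytic biconcave (discocyte) surface -------------------------------

# Half-thickness of the classic discocyte profile at radial position rho,
# for resting diameter d0: z(rho) = (d0/4) sqrt(1-r^2) (c0 + c1 r^2 +
# c2 r^4) with r = 2 rho / d0 (dimple thickness 2 z(0) = 0.81 um, maximum
# thickness ~2.4 um at d0 = 7.82 um).
biconcave_halfz <- function(rho, d0 = 7.82, c0 = 0.207, c1 = 2.003,
                            c2 = -1.123) {
  r2 <- pmin((2 * rho / d0)^2, 1)
  0.25 * d0 * sqrt(1 - r2) * (c0 + c1 * r2 + c2 * r2^2)
}

# Map unit-sphere points to the discocyte: polar angle -> radial position.
to_biconcave <- function(verts, d0 = 7.82) {
  rho_s <- sqrt(verts[, 1]^2 + verts[, 2]^2)
  rho <- 0.5 * d0 * rho_s
  zsign <- sign(verts[, 3])
  zsign[zsign == 0] <- 0
  z <- zsign * biconcave_halfz(rho, d0)
  sc <- ifelse(rho_s > 1e-12, rho / rho_s, 0)
  cbind(verts[, 1] * sc, verts[, 2] * sc, z)
}

# Analytic area/volume of the discocyte (surface of revolution), by dense
# quadrature over the smooth theta-parametrisation rho = R sin(theta),
# z = R cos(theta) (c0 + c1 sin^2 + c2 sin^4); serves as the independent
# oracle for the mesh integration.
biconcave_area_volume_quadrature <- function(d0 = 7.82, c0 = 0.207,
                                             c1 = 2.003, c2 = -1.123) {
  R <- d0 / 2
  rho <- function(th) R * sin(th)
  drho <- function(th) R * cos(th)
  zf <- function(th) {
    s2 <- sin(th)^2
    0.5 * R * cos(th) * (c0 + c1 * s2 + c2 * s2^2)
  }
  dz <- function(th) {
    s <- sin(th); cth <- cos(th); s2 <- s^2
    0.5 * R * (-s * (c0 + c1 * s2 + c2 * s2^2) +
                 cth * (2 * c1 * s * cth + 4 * c2 * s2 * s * cth))
  }
  area <- 2 * stats::integrate(function(th)
    2 * pi * rho(th) * sqrt(drho(th)^2 + dz(th)^2), 0, pi / 2,
    rel.tol = 1e-10)$value
  vol <- 2 * stats::integrate(function(th)
    2 * pi * rho(th) * zf(th) * drho(th), 0, pi / 2,
    rel.tol = 1e-10)$value
  c(area = area, volume = vol)
}

# ---- shape deformation maps ----------------------------------------------

# Deformation maps for the four morphologies. `bic` are the discocyte
# vertices, `sphere` the generating unit-sphere vertices (used by the
# quasi-spherical and crescent shapes).
apply_shape_map <- function(bic, sphere, shape, seed) {
  switch(shape,
    biconcave = bic,
    elongated = cbind(4.5 * sphere[, 1], 1.6 * sphere[, 2], sphere[, 3]),
    granular = {
      # quasi-spherical shrink with a deterministic surface perturbation
      ph <- 2 * pi * ((seed %% 1009) / 1009)
      th <- acos(pmin(1, pmax(-1, sphere[, 3])))
      phi <- atan2(sphere[, 2], sphere[, 1])
      bump <- 1 + 0.10 * sin(3 * th)^2 * cos(4 * phi + ph) +
        0.06 * cos(2 * th) * sin(3 * phi - ph)
      g <- sphere * bump * 2.2
      cbind(g[, 1], g[, 2], 0.62 * g[, 3])
    },
    sickle = {
      # curved crescent: bent elongated ellipsoid
      el <- cbind(5.0 * sphere[, 1], 1.0 * sphere[, 2], 1.3 * sphere[, 3])
      rb <- 4.5  # bend radius of the crescent midline, um
      cbind((rb - el[, 3]) * sin(el[, 1] / rb), el[, 2],
            rb - (rb - el[, 3]) * cos(el[, 1] / rb))
    },
    stop("unknown shape: ", shape))
}

# Two-parameter rescale (uniform scale + thin-axis scale) driving mesh area
# and volume to the targets by damped Newton iteration on the mesh itself.
rescale_to_targets <- function(verts, tris, target_area, target_volume,
                               axis = 3L, tol = 1e-10, max_iter = 80L) {
  sv <- function(p) {
    v <- verts * exp(p[1])
    v[, axis] <- v[, axis] * exp(p[2])
    mesh_area_volume(list(vertices = v, triangles = tris))
  }
  p <- c(0, 0)
  for (it in seq_len(max_iter)) {
    f <- sv(p)
    r <- c(log(f["area"] / target_area), log(f["volume"] / target_volume))
    if (max(abs(r)) < tol) break
    d <- 1e-6
    j1 <- (c(log(sv(p + c(d, 0))["area"]), log(sv(p + c(d, 0))["volume"])) -
             c(log(f["area"]), log(f["volume"]))) / d
    j2 <- (c(log(sv(p + c(0, d))["area"]), log(sv(p + c(0, d))["volume"])) -
             c(log(f["area"]), log(f["volume"]))) / d
    J <- cbind(j1, j2)
    step <- tryCatch(solve(J, r), error = function(e) r * 0.5)
    step <- pmin(pmax(step, -0.5), 0.5)
    p <- p - step
  }
  v <- verts * exp(p[1])
  v[, axis] <- v[, axis] * exp(p[2])
  v
}

#' Generate an RBC surface mesh
#'
#' Builds a closed triangulated surface of the requested morphology with the
#' requested surface area and volume (each within 0.01% after iterative
#' rescaling; well inside the 1% contract). The biconcave shape is the
#' classic discocyte profile; elongated, granular and sickle morphologies are
#' smooth deformation maps of it (axial stretch; quasi-spherical shrink with
#' surface bumps; curved-crescent bend), each followed by area/volume
#' retargeting. The construction is deterministic given (spec, seed).
#'
#' @param spec a [cell_shape_spec()].
#' @param seed integer; fixes the phase of the granular surface perturbation.
#' @return a [tri_mesh()]. With `n_vertices = 500` the mesh has 996
#'   triangles and 1494 edges.
#' @export
make_rbc_mesh <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cell_shape_spec"))
  sph <- unit_sphere_mesh(spec$n_vertices)
  verts <- to_biconcave(sph$vertices)
  verts <- apply_shape_map(verts, sph$vertices, spec$shape,
                           as.integer(seed))
  # the free thickness axis of the retargeting: width (y) for the crescent,
  # thickness (z) otherwise
  axis <- if (spec$shape == "sickle") 2L else 3L
  verts <- rescale_to_targets(verts, sph$triangles, spec$target_area,
                              spec$target_volume, axis = axis)
  mesh <- tri_mesh(verts, sph$triangles, validate = FALSE)
  validate_mesh(mesh)  # internal consistency: never silently return junk
  av <- mesh_area_volume(mesh)
  if (abs(av[1] / spec$target_area - 1) > 0.01 ||
      abs(av[2] / spec$target_volume - 1) > 0.01)
    stop("internal error: area/volume retargeting failed to converge")
  mesh
}

#' Generate a wall-adhered macrophage mesh
#'
#' Spherical-cap surface of apex height `cap_height` closed by a flat base
#' disc on the wall plane z = 0, centred at `base_center`.
#'
#' @param spec a [macrophage_spec()].
#' @param n_vertices approximate vertex budget (exact count may differ by a
#'   few vertices due to ring quantisation).
#' @return a [tri_mesh()].
#' @export
make_macrophage_mesh <- function(spec, n_vertices = 500L) {
  stopifnot(inherits(spec, "macrophage_spec"))
  R <- spec$radius; hM <- spec$cap_height
  z0 <- hM - R                      # sphere centre height
  if (hM >= 2 * R - 1e-9) {
    # full sphere tangent to the wall
    sph <- unit_sphere_mesh(as.integer(n_vertices))
    v <- sph$vertices * R
    v[, 3] <- v[, 3] + R
    v[, 1] <- v[, 1] + spec$base_center[1]
    v[, 2] <- v[, 2] + spec$base_center[2]
    return(tri_mesh(v, sph$triangles))
  }
  th_rim <- acos(max(-1, min(1, -z0 / R)))  # polar angle of the wall rim
  r_rim <- R * sin(th_rim)
  # split the vertex budget between cap and base disc by area share
  a_cap <- 2 * pi * R * hM
  a_disc <- pi * r_rim^2
  n_cap <- max(20L, round((n_vertices - 2) * a_cap / (a_cap + a_disc)))
  n_disc <- max(10L, n_vertices - 2L - n_cap)
  # cap rings (from apex down), last ring is the rim
  kc <- max(2L, round(sqrt(n_cap / 2)))
  thc <- th_rim * seq_len(kc) / kc
  wc <- sin(thc)
  nc <- pmax(6L, round(n_cap * wc / sum(wc)))
  # disc rings (from rim radius inward), exclude rim itself
  kd <- max(1L, round(sqrt(n_disc / 4)))
  rd <- r_rim * (kd:1) / (kd + 1)
  nd <- pmax(6L, round(n_disc * rd / sum(rd)))
  verts <- list(c(0, 0, z0 + R))    # apex
  rings <- list()
  phis <- list()
  nxt <- 2L
  mk_ring <- function(rad, z, ni, stag) {
    phi <- 2 * pi * (seq_len(ni) - 1 + 0.5 * stag) / ni
    list(xyz = cbind(rad * cos(phi), rad * sin(phi), rep(z, ni)), phi = phi)
  }
  allr <- list()
  for (i in seq_len(kc))
    allr[[i]] <- mk_ring(R * sin(thc[i]), z0 + R * cos(thc[i]), nc[i], i %% 2)
  for (j in seq_len(kd))
    allr[[kc + j]] <- mk_ring(rd[j], 0, nd[j], (kc + j) %% 2)
  nall <- length(allr)
  V <- do.call(rbind, c(list(matrix(c(0, 0, z0 + R), 1)),
                        lapply(allr, `[[`, "xyz"),
                        list(matrix(c(0, 0, 0), 1))))
  idx <- vector("list", nall)
  nxt <- 2L
  for (i in seq_len(nall)) {
    ni <- nrow(allr[[i]]$xyz)
    idx[[i]] <- nxt:(nxt + ni - 1L)
    nxt <- nxt + ni
  }
  ctr <- nxt  # wall-plane centre point
  tris <- list()
  i1 <- idx[[1]]; n1 <- length(i1)
  tris[[1]] <- cbind(rep(1L, n1), i1, i1[c(2:n1, 1)])
  for (i in seq_len(nall - 1))
    tris[[i + 1]] <- zip_rings(idx[[i]], allr[[i]]$phi,
                               idx[[i + 1]], allr[[i + 1]]$phi)
  ik <- idx[[nall]]; nk <- length(ik)
  tris[[nall + 1]] <- cbind(rep(ctr, nk), ik[c(2:nk, 1)], ik)
  tr <- orient_outward(V, do.call(rbind, tris))
  V[, 1] <- V[, 1] + spec$base_center[1]
  V[, 2] <- V[, 2] + spec$base_center[2]
  tri_mesh(V, tr)
}

#' Icosphere (subdivided icosahedron)
#'
#' Utility mesh with analytically known limits; used as a reference surface
#' in validation.
#'
#' @param subdiv number of 4-to-1 subdivisions.
#' @param radius sphere radius.
#' @return a [tri_mesh()].
#' @export
icosphere <- function(subdiv = 3L, radius = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid <- new.env()
    vv <- v
    key <- function(a, b) paste(min(a, b), max(a, b))
    getmid <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid[[k]])) return(mid[[k]])
      p <- (vv[a, ] + vv[b, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      mid[[k]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, cc); ca <- getmid(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
      vv <- v
    }
    f <- nf
  }
  tri_mesh(v * radius, f)
}

# ---- mesh I/O: OFF and legacy VTK polydata --------------------------------

#' Write a mesh to OFF format
#' @param mesh a [tri_mesh()].
#' @param path output file.
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d %d", nrow(mesh$vertices), nrow(mesh$triangles),
                     nrow(mesh$edges)), con)
  writeLines(sprintf("%.10g %.10g %.10g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' Read a mesh from OFF format
#' @param path OFF file.
#' @return a [tri_mesh()].
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file")
  hd <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- hd[1]; nf <- hd[2]
  vl <- lines[3:(2 + nv)]
  fl <- lines[(3 + nv):(2 + nv + nf)]
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    x <- as.integer(x)
    if (x[1] != 3L) stop("only triangle faces supported")
    x[2:4] + 1L
  }))
  tri_mesh(v, f)
}

#' Write a mesh as legacy VTK ASCII polydata
#' @param mesh a [tri_mesh()].
#' @param path output file.
#' @export
write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "splenosim mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(mesh$vertices))), con)
  writeLines(sprintf("%.10g %.10g %.10g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  nf <- nrow(mesh$triangles)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                     mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
  invisible(path)
}

#' Read a legacy VTK ASCII polydata mesh
#' @param path VTK file written by [write_mesh_vtk()] or compatible.
#' @return a [tri_mesh()].
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  nv <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  nums <- as.numeric(unlist(strsplit(trimws(lines[(ip + 1):(ip + nv)]),
                                     "\\s+")))
  v <- matrix(nums[1:(3 * nv)], ncol = 3, byrow = TRUE)
  ig <- grep("^POLYGONS", lines)[1]
  nf <- as.integer(strsplit(lines[ig], "\\s+")[[1]][2])
  fl <- lines[(ig + 1):(ig + nf)]
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    x <- as.integer(x)
    x[2:4] + 1L
  }))
  tri_mesh(v, f)
}

# Simple per-shape qualitative morphology metrics used in checks/config.
shape_metrics <- function(mesh) {
  v <- mesh$vertices
  ext <- apply(v, 2, function(x) diff(range(x)))
  list(extent = ext, aspect_xy = ext[1] / ext[2], aspect_xz = ext[1] / ext[3])
}
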