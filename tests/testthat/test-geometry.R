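# Mesh synthesis: manifoldness, Euler characteristic, area/volume control,
# morphology maps, macrophage caps, and text I/O.

test_that("all four RBC morphologies mesh to the target area and volume", {
  for (sh in c("biconcave", "elongated", "granular", "sickle")) {
    m <- make_rbc_mesh(cell_shape_spec(sh), seed = 7)
    expect_true(validate_mesh(m))
    av <- mesh_area_volume(m)
    expect_lt(abs(av["area"] / 132.87 - 1), 0.01)
    expect_lt(abs(av["volume"] / 92.46 - 1), 0.01)
    nV <- nrow(m$vertices); nE <- nrow(m$edges); nF <- nrow(m$triangles)
    expect_identical(nV - nE + nF, 2L)
  }
})

test_that("the default biconcave mesh reproduces the reference counts", {
  m <- make_rbc_mesh(cell_shape_spec("biconcave"), seed = 1)
  expect_identical(nrow(m$vertices), 500L)
  expect_identical(nrow(m$triangles), 996L)
  expect_identical(nrow(m$edges), 1494L)
})

test_that("mesh generation is deterministic and seed-sensitive where meant", {
  a <- make_rbc_mesh(cell_shape_spec("granular"), seed = 3)
  b <- make_rbc_mesh(cell_shape_spec("granular"), seed = 3)
  c <- make_rbc_mesh(cell_shape_spec("granular"), seed = 4)
  expect_identical(a$vertices, b$vertices)
  expect_false(identical(a$vertices, c$vertices))
})

test_that("infeasible area/volume pairs are rejected up front", {
  # a sphere of volume 92.46 um^3 needs at least ~98.8 um^2 of area
  expect_error(cell_shape_spec("biconcave", target_area = 90,
                               target_volume = 92.46), "infeasible")
})

test_that("morphologies are qualitatively distinct", {
  ext <- sapply(c("biconcave", "elongated", "granular", "sickle"),
                function(sh) {
                  m <- make_rbc_mesh(cell_shape_spec(sh), 1)
                  apply(m$vertices, 2, function(x) diff(range(x)))
                })
  # elongated is the longest and strongly anisotropic in-plane
  expect_gt(ext[1, "elongated"] / ext[2, "elongated"], 2)
  # granular is isotropic in-plane (bumpy oblate blob)
  expect_lt(abs(ext[1, "granular"] / ext[2, "granular"] - 1), 0.1)
  # sickle is thick in z (curved crescent), biconcave flat
  expect_gt(ext[3, "sickle"], 1.5 * ext[3, "biconcave"])
  # biconcave has its dimple on the axis: thinner at the centre than at
  # mid-radius
  m <- make_rbc_mesh(cell_shape_spec("biconcave"), 1)
  rho <- sqrt(m$vertices[, 1]^2 + m$vertices[, 2]^2)
  expect_lt(max(abs(m$vertices[rho < 1, 3])),
            max(abs(m$vertices[rho > 2 & rho < 3, 3])))
})

test_that("biconcave mesh integrals agree with the analytic quadrature", {
  q <- splenosim:::biconcave_area_volume_quadrature()
  sph <- splenosim:::unit_sphere_mesh(2000)
  raw <- splenosim:::to_biconcave(sph$vertices)
  av <- mesh_area_volume(list(vertices = raw, triangles = sph$triangles))
  expect_lt(abs(av["area"] / q["area"] - 1), 0.005)
  expect_lt(abs(av["volume"] / q["volume"] - 1), 0.005)
})

test_that("macrophage cap geometry is controlled", {
  spec <- macrophage_spec(radius = 11, cap_height = 11)
  m <- make_macrophage_mesh(spec, 2000)
  expect_true(validate_mesh(m))
  expect_lt(abs(max(m$vertices[, 3]) / 11 - 1), 0.01)
  # closed-form: lateral cap area + base disc
  analytic <- 2 * pi * 11 * 11 + pi * (2 * 11 * 11 - 11^2)
  expect_lt(abs(mesh_area_volume(m)["area"] / analytic - 1), 0.01)
  expect_error(macrophage_spec(radius = 9, cap_height = 19), "infeasible")
  expect_error(macrophage_spec(radius = 5, cap_height = 5), "outside")
})

test_that("the full-sphere cap limit recovers the sphere area", {
  spec <- macrophage_spec(radius = 8, cap_height = 16)
  m <- make_macrophage_mesh(spec, 1500)
  expect_lt(abs(mesh_area_volume(m)["area"] / (4 * pi * 64) - 1), 0.01)
})

test_that("mesh_area_volume matches analytic and decomposition oracles", {
  iso <- icosphere(5)
  av <- mesh_area_volume(iso)
  expect_lt(abs(av["area"] / (4 * pi) - 1), 0.005)
  expect_lt(abs(av["volume"] / (4 * pi / 3) - 1), 0.005)
  # random convex polyhedron: affine image of an icosphere; oracle = fan of
  # signed tetrahedra from a random interior point
  set.seed(42)
  A <- matrix(rnorm(9, sd = 0.4), 3) + diag(3)
  v <- icosphere(2)$vertices %*% A
  tr <- icosphere(2)$triangles
  av2 <- mesh_area_volume(list(vertices = v, triangles = tr))
  p0 <- colMeans(v) + rnorm(3, sd = 0.05)
  fan <- 0
  for (k in seq_len(nrow(tr))) {
    a <- v[tr[k, 1], ] - p0; b <- v[tr[k, 2], ] - p0; cc <- v[tr[k, 3], ] - p0
    fan <- fan + det(cbind(a, b, cc)) / 6
  }
  expect_lt(abs(av2["volume"] - fan) / abs(fan), 1e-10)
})

test_that("open meshes are rejected", {
  iso <- icosphere(1)
  expect_error(tri_mesh(iso$vertices, iso$triangles[-1, ]), "closed|manifold")
})

test_that("OFF and VTK export/import round-trip", {
  m <- make_rbc_mesh(cell_shape_spec(n_vertices = 120), 1)
  f1 <- tempfile(fileext = ".off"); f2 <- tempfile(fileext = ".vtk")
  write_mesh_off(m, f1)
  write_mesh_vtk(m, f2)
  m1 <- read_mesh_off(f1)
  m2 <- read_mesh_vtk(f2)
  expect_equal(m1$vertices, m$vertices, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(m1$triangles, m$triangles)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(m2$triangles, m$triangles)
})

test_that("exported meshes open in an independent reader (trimesh)", {
  m <- make_rbc_mesh(cell_shape_spec(n_vertices = 200), 1)
  f <- tempfile(fileext = ".off")
  write_mesh_off(m, f)
  script <- sprintf(paste0(
    "import trimesh, json; m = trimesh.load('%s');",
    "print(json.dumps({'v': len(m.vertices), 'f': len(m.faces),",
    "'watertight': bool(m.is_watertight), 'area': float(m.area),",
    "'volume': float(abs(m.volume))}))"), f)
  out <- tryCatch(system2("python", c("-c", shQuote(script)), stdout = TRUE,
                          stderr = TRUE),
                  error = function(e) NULL)
  skip_if(is.null(out) || length(out) == 0 || !grepl("^\\{", out[length(out)]),
          "python/trimesh unavailable")
  res <- jsonlite::fromJSON(out[length(out)])
  expect_identical(res$v, 200L)
  expect_identical(res$f, nrow(m$triangles))
  expect_true(res$watertight)
  av <- mesh_area_volume(m)
  expect_lt(abs(res$area / av["area"] - 1), 1e-6)
  expect_lt(abs(res$volume / av["volume"] - 1), 1e-6)
})

test_that("2D outlines are closed, CCW and area-matched across shapes", {
  a_ref <- attr(make_cell_outline("biconcave"), "area")
  for (sh in c("biconcave", "elongated", "granular", "sickle")) {
    o <- make_cell_outline(sh, 40)
    expect_identical(nrow(o), 40L)
    expect_gt(splenosim:::polygon_area(o), 0)
    expect_lt(abs(attr(o, "area") / a_ref - 1), 1e-9)
  }
})
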