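test_that("hexagonal (1,1) folds to the truncated icosahedron", {
  m <- build_polyhedron(capsid_design("hexagonal", 1, 1))
  cen <- mesh_census(m)
  expect_identical(c(cen$V, cen$E, cen$F), c(60L, 90L, 32L))
  expect_identical(cen$vertex_polygons, 12L)
  expect_identical(cen$hexagons, 20L)
  # every vertex polygon is a planar regular pentagon
  vp <- which(m$labels == "vertex_polygon")
  expect_true(all(lengths(m$faces[vp]) == 5L))
})

test_that("trihexagonal (1,0) folds to the icosidodecahedron", {
  cen <- mesh_census(build_polyhedron(capsid_design("trihexagonal", 1, 0)))
  expect_identical(c(cen$V, cen$E, cen$F), c(30L, 60L, 32L))
  expect_identical(c(cen$vertex_polygons, cen$triangles), c(12L, 20L))
})

test_that("hexagonal (2,0) reproduces the T=4 capsomer layout", {
  cen <- mesh_census(build_polyhedron(capsid_design("hexagonal", 2, 0)))
  expect_identical(c(cen$vertex_polygons, cen$hexagons), c(12L, 30L))
})

test_that("snub (1,0) enantiomorphs agree in census and measures", {
  m1 <- build_polyhedron(capsid_design("snub_hexagonal", 1, 0))
  m2 <- build_polyhedron(capsid_design("snub_hexagonal", 1, 0), mirror = TRUE)
  c1 <- mesh_census(m1); c2 <- mesh_census(m2)
  expect_identical(c(c1$V, c1$E, c1$F), c(60L, 150L, 92L))
  expect_identical(c(c1$V, c1$E, c1$F), c(c2$V, c2$E, c2$F))
  expect_equal(mesh_measures(m1)$volume, mesh_measures(m2)$volume,
               tolerance = 1e-12)
  # the mirrored vertex set is the x-reflection of the original
  expect_equal(max_nn_dist(m2$vertices,
                           cbind(-m1$vertices[, 1], m1$vertices[, -1])),
               0, tolerance = 1e-9)
})

test_that("octahedral snub (1,0) folds to the snub cube", {
  cen <- mesh_census(build_polyhedron(
    capsid_design("snub_hexagonal", 1, 0, symmetry = "octahedral")))
  expect_identical(c(cen$V, cen$E, cen$F), c(24L, 60L, 38L))
  expect_identical(c(cen$vertex_polygons, cen$triangles), c(6L, 32L))
})

test_that("built meshes match the closed-form census (spot designs)", {
  for (case in list(list("trihexagonal", 2, 1, "icosahedral"),
                    list("rhombitrihexagonal", 1, 1, "icosahedral"),
                    list("snub_hexagonal", 1, 1, "octahedral"),
                    list("hexagonal", 3, 1, "icosahedral"))) {
    d <- capsid_design(case[[1]], case[[2]], case[[3]], symmetry = case[[4]])
    mc <- mesh_census(build_polyhedron(d))
    fc <- face_census(d)
    for (f in c("vertex_polygons", "hexagons", "triangles", "squares",
                "V", "E", "F"))
      expect_identical(mc[[f]], fc[[f]],
                       label = paste(case[[4]], case[[1]], f))
  }
})

test_that("duals have one tile per primal vertex and a single tile type", {
  m <- build_polyhedron(capsid_design("trihexagonal", 1, 1, dual = TRUE))
  expect_identical(length(m$faces), 90L)          # 90 rhombs (MS2)
  expect_identical(unique(m$labels), "rhomb")
  expect_true(all(lengths(m$faces) == 4L))
  m <- build_polyhedron(capsid_design("rhombitrihexagonal", 1, 0, dual = TRUE))
  expect_identical(length(m$faces), 60L)          # 60 kites
  expect_identical(unique(m$labels), "kite")
  expect_true(all(lengths(m$faces) == 4L))
  m <- build_polyhedron(capsid_design("snub_hexagonal", 1, 0, dual = TRUE))
  expect_identical(length(m$faces), 60L)          # 60 floret pentagons
  expect_true(all(lengths(m$faces) == 5L))
})

test_that("dual of dual is combinatorially isomorphic to the primal", {
  for (kind in c("hexagonal", "trihexagonal", "rhombitrihexagonal")) {
    p <- build_polyhedron(capsid_design(kind, 1, 1))
    dd <- build_dual(build_dual(p))
    cp <- mesh_census(p); cdd <- mesh_census(dd)
    expect_identical(c(cp$V, cp$E, cp$F), c(cdd$V, cdd$E, cdd$F), label = kind)
    expect_identical(sort(table(lengths(p$faces))),
                     sort(table(lengths(dd$faces))), label = kind)
  }
})

test_that("icosahedron volume matches the classical closed form", {
  ico <- build_dual(build_polyhedron(capsid_design("hexagonal", 1, 0)))
  a <- sqrt(sum((ico$vertices[ico$faces[[1]][1], ] -
                   ico$vertices[ico$faces[[1]][2], ])^2))
  expect_equal(mesh_measures(ico)$volume, (5 / 12) * (3 + sqrt(5)) * a^3,
               tolerance = 1e-9)
})

test_that("measured area ratio trihex/hex at (2,1) is alpha_t within 2%", {
  a <- mesh_measures(build_polyhedron(capsid_design("trihexagonal", 2, 1)))
  b <- mesh_measures(build_polyhedron(capsid_design("hexagonal", 2, 1)))
  expect_equal(a$surface_area / b$surface_area, 4 / 3, tolerance = 0.02)
})

test_that("icosahedral meshes admit 5-fold rotations about symmetry vertices", {
  m <- build_polyhedron(capsid_design("trihexagonal", 2, 1))
  vp <- which(m$labels == "vertex_polygon")[1]
  axis <- colMeans(m$vertices[m$faces[[vp]], , drop = FALSE])
  R <- rotation_about(axis, 2 * pi / 5)
  expect_equal(max_nn_dist(m$vertices %*% t(R), m$vertices), 0,
               tolerance = 1e-9)
})

test_that("octahedral meshes admit 4-fold rotations about symmetry vertices", {
  m <- build_polyhedron(capsid_design("rhombitrihexagonal", 1, 1,
                                      symmetry = "octahedral"))
  vp <- which(m$labels == "vertex_polygon")[1]
  axis <- colMeans(m$vertices[m$faces[[vp]], , drop = FALSE])
  R <- rotation_about(axis, pi / 2)
  expect_equal(max_nn_dist(m$vertices %*% t(R), m$vertices), 0,
               tolerance = 1e-9)
})

test_that("sphere projection preserves census and equalizes radii", {
  d <- capsid_design("trihexagonal", 2, 0)
  m <- build_polyhedron(d, project_to_sphere = TRUE)
  mc <- mesh_census(m); fc <- face_census(d)
  expect_identical(c(mc$V, mc$E, mc$F), c(fc$V, fc$E, fc$F))
  r <- sqrt(rowSums(m$vertices^2))
  expect_equal(diff(range(r)), 0, tolerance = 1e-9)
})

test_that("build_polyhedron validates its design argument", {
  expect_error(build_polyhedron("trihexagonal"), "capsid_design")
})
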