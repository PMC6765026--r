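A0 <- 3 * sqrt(3) / 4
HEX_AREA <- 3 * sqrt(3) / 2
TRI_AREA <- sqrt(3) / 4

test_that("triangulation numbers follow h^2 + hk + k^2", {
  expect_identical(t_number(1, 1), 3L)
  expect_identical(t_number(2, 1), 7L)
  expect_identical(t_number(4, 0), 16L)
  for (hk in hk_grid(4))
    expect_identical(t_number(hk[1], hk[2]), t_number(hk[2], hk[1]))
})

test_that("scaled T-numbers and labels match the lattice scaling factors", {
  expect_equal(t_scaled("trihexagonal", 3, 0), 12, tolerance = 1e-14)
  expect_equal(t_scaled("snub", 1, 1), 7, tolerance = 1e-14)
  expect_equal(t_scaled("trihexagonal", 2, 1), 28 / 3, tolerance = 1e-14)
  expect_identical(t_label("trihexagonal", 3, 0), "T_t(3,0)=12")
  expect_identical(t_label("trihexagonal", 2, 1), "T_t(2,1)=28/3")
  expect_identical(t_label("trihexagonal", 1, 0), "T_t(1,0)=4/3")
  expect_identical(t_label("hexagonal", 1, 1), "T(1,1)=3")
  expect_identical(t_label("rhombitrihexagonal", 1, 0, dual = TRUE),
                   "T_r^D(1,0)=2.49")
})

test_that("closed-form censuses satisfy Euler's relation for h,k <= 4", {
  for (sym in c("icosahedral", "octahedral"))
    for (kind in all_kinds) for (hk in hk_grid(4)) {
      cen <- face_census(capsid_design(kind, hk[1], hk[2], symmetry = sym))
      expect_identical(cen$V - cen$E + cen$F, 2L,
                       label = sprintf("%s %s (%d,%d)", sym, kind, hk[1], hk[2]))
      expect_identical(cen$F, cen$vertex_polygons + cen$hexagons +
                         cen$triangles + cen$squares)
      expect_identical(cen$dual_tiles, cen$V)
    }
})

test_that("T = 1 censuses are the eight named Archimedean solids", {
  # (kind, symmetry) -> c(V, E, F)
  truth <- list(
    list("hexagonal", "icosahedral", c(20L, 30L, 12L)),          # dodecahedron
    list("trihexagonal", "icosahedral", c(30L, 60L, 32L)),       # icosidodecahedron
    list("snub_hexagonal", "icosahedral", c(60L, 150L, 92L)),    # snub dodecahedron
    list("rhombitrihexagonal", "icosahedral", c(60L, 120L, 62L)), # rhombicosidodecahedron
    list("hexagonal", "octahedral", c(8L, 12L, 6L)),             # cube
    list("trihexagonal", "octahedral", c(12L, 24L, 14L)),        # cuboctahedron
    list("snub_hexagonal", "octahedral", c(24L, 60L, 38L)),      # snub cube
    list("rhombitrihexagonal", "octahedral", c(24L, 48L, 26L)))  # rhombicuboctahedron
  for (tt in truth) {
    cen <- face_census(capsid_design(tt[[1]], 1, 0, symmetry = tt[[2]]))
    expect_identical(c(cen$V, cen$E, cen$F), tt[[3]],
                     label = paste(tt[[2]], tt[[1]]))
  }
  # snub dodecahedron details: 12 pentagons + 80 triangles
  cen <- face_census(capsid_design("snub_hexagonal", 1, 0))
  expect_identical(c(cen$vertex_polygons, cen$triangles), c(12L, 80L))
  # rhombicosidodecahedron: 12 pentagons, 20 triangles, 30 squares
  cen <- face_census(capsid_design("rhombitrihexagonal", 1, 0))
  expect_identical(c(cen$triangles, cen$squares), c(20L, 30L))
})

test_that("hexagonal T(1,1) is the truncated icosahedron (buckyball)", {
  cen <- face_census(capsid_design("hexagonal", 1, 1))
  expect_identical(c(cen$vertex_polygons, cen$hexagons), c(12L, 20L))
})

test_that("census area bookkeeping reproduces the total facet area", {
  # each symmetry vertex retains 5/6 (icosahedral) or 4/6 (octahedral) of a
  # hexagon; summed face areas must equal n_facets * alpha * T * A0
  for (sym in c("icosahedral", "octahedral")) {
    sc <- symmetry_class(sym)
    for (kind in all_kinds) for (hk in hk_grid(3)) {
      cen <- face_census(capsid_design(kind, hk[1], hk[2], symmetry = sym))
      Tn <- t_number(hk[1], hk[2])
      total <- cen$vertex_polygons * sc$vertex_wedge_fraction * HEX_AREA +
        cen$hexagons * HEX_AREA + cen$triangles * TRI_AREA + cen$squares * 1
      expect_equal(total, sc$n_facets * alpha_factor(kind) * Tn * A0,
                   tolerance = 1e-12,
                   label = sprintf("%s %s (%d,%d)", sym, kind, hk[1], hk[2]))
    }
  }
})

test_that("strict trihexagonal stoichiometry gives equal MCP and mCP counts", {
  # Basilisk: T_t(3,0) = 12, 1080 = 540 + 540
  st <- stoichiometry(capsid_design("trihexagonal", 3, 0))
  expect_identical(c(st$n_MCP, st$n_mCP, st$n_total), c(540L, 540L, 1080L))
  # HSV-1: T_t(4,0) = 64/3, 960 MCP + 960 mCP
  st <- stoichiometry(capsid_design("trihexagonal", 4, 0,
                                    convention = "trihex_edge_to_edge"))
  expect_identical(c(st$n_MCP, st$n_mCP), c(960L, 960L))
  # edge-to-edge total doubles the CK total at equal T
  for (hk in hk_grid(4)) {
    a <- stoichiometry(capsid_design("trihexagonal", hk[1], hk[2]))$n_total
    b <- stoichiometry(capsid_design("hexagonal", hk[1], hk[2]))$n_total
    expect_identical(a, 2L * b)
  }
})

test_that("gyrated trihexagonal designs drop the MCP/mCP distinction", {
  st <- stoichiometry(capsid_design("trihexagonal", 1, 0,
                                    convention = "gyrated_trihex"))
  expect_identical(st$n_total, 120L)  # phi6 inner capsid, pseudo T=2
  expect_identical(st$n_mCP, 0L)
})

test_that("dual tiling stoichiometries follow the per-tile counts", {
  # MS2: 90 rhomb tiles = 90 dimers = 180 proteins
  st <- stoichiometry(capsid_design("trihexagonal", 1, 1, dual = TRUE,
                                    convention = "rhomb_order_2"))
  expect_identical(st$breakdown$multiplicity, 90L)
  expect_identical(st$n_total, 180L)
  # Zika: 30 rhomb tiles of 3 dimers = 180 proteins
  st <- stoichiometry(capsid_design("trihexagonal", 1, 0, dual = TRUE,
                                    convention = "rhomb_order_6"))
  expect_identical(st$breakdown$multiplicity, 30L)
  expect_identical(st$n_total, 180L)
  # picobirnavirus-type order-4 series: 120 T proteins
  st <- stoichiometry(capsid_design("trihexagonal", 2, 0, dual = TRUE,
                                    convention = "rhomb_order_4"))
  expect_identical(st$n_total, 480L)
  # Tobacco ringspot: 60 kite protomers of 3 domains
  st <- stoichiometry(capsid_design("rhombitrihexagonal", 1, 0, dual = TRUE))
  expect_identical(st$breakdown$multiplicity, 60L)
  expect_identical(st$n_total, 180L)
  # hexagonal dual: triangle trimers, 60 T proteins
  st <- stoichiometry(capsid_design("hexagonal", 1, 1, dual = TRUE))
  expect_identical(st$n_total, 180L)
  # floret count is a parameter
  d <- capsid_design("snub_hexagonal", 1, 0, dual = TRUE)
  expect_identical(stoichiometry(d)$n_total, 360L)
  expect_identical(stoichiometry(d, n_per_tile = 3)$n_total, 180L)
})

test_that("primal snub and rhombitrihexagonal designs are flagged hypothetical", {
  expect_true(stoichiometry(capsid_design("snub_hexagonal", 1, 0))$hypothetical)
  expect_true(stoichiometry(capsid_design("rhombitrihexagonal", 1, 0))$hypothetical)
  expect_false(stoichiometry(capsid_design("trihexagonal", 1, 0))$hypothetical)
})

test_that("incompatible convention/design pairings are rejected by name", {
  expect_error(capsid_design("hexagonal", 1, 0, convention = "rhomb_order_2"),
               "rhomb_order_2.*hexagonal")
  expect_error(capsid_design("trihexagonal", 1, 0, dual = TRUE,
                             convention = "kite_protomer"),
               "kite_protomer.*trihexagonal")
  expect_error(capsid_design("hexagonal", 1, 0, convention = "no_such"),
               "unknown tile convention")
})

test_that("size scalings follow the alpha*T area ratios", {
  ss <- size_scaling(capsid_design("trihex", 2, 1), capsid_design("hex", 2, 1))
  expect_equal(ss$area_ratio, 4 / 3, tolerance = 1e-14)
  expect_equal(ss$volume_ratio, (4 / 3)^1.5, tolerance = 1e-14)
  ss <- size_scaling(capsid_design("rhombi", 1, 0, dual = TRUE),
                     capsid_design("hex", 1, 1, dual = TRUE))
  expect_equal(ss$radius_ratio, sqrt((4 / 3 + 2 / sqrt(3)) / 3),
               tolerance = 1e-14)
  d <- capsid_design("snub", 2, 1)
  ss <- size_scaling(d, d)
  expect_equal(c(ss$area_ratio, ss$radius_ratio, ss$volume_ratio), c(1, 1, 1))
})

test_that("the catalog interleaves the new designs between the CK sizes", {
  cat_df <- enumerate_designs(3, conventions = "ck_strict")
  lab <- cat_df$T_label
  expect_true(all(c("T_t(1,0)=4/3", "T_s(1,0)=7/3", "T_r(1,0)=2.49") %in% lab))
  mid <- cat_df[cat_df$T_label %in%
                  c("T_t(1,0)=4/3", "T_s(1,0)=7/3", "T_r(1,0)=2.49"), ]
  expect_true(all(mid$T_scaled > 1 & mid$T_scaled < 3))
  expect_false(is.unsorted(cat_df$T_scaled))
})

test_that("classical CK protein totals are 60, 180, 240, 420", {
  cat_df <- enumerate_designs(7, kinds = "hexagonal", conventions = "ck_strict")
  expect_identical(cat_df$n_total, c(60L, 180L, 240L, 420L))
})

test_that("T_t(1,1) = 4 shares its size with T(2,0) = 4", {
  cat_df <- enumerate_designs(4, kinds = c("hexagonal", "trihexagonal"),
                              conventions = "ck_strict")
  t4 <- cat_df[abs(cat_df$T_scaled - 4) < 1e-12, ]
  expect_setequal(t4$T_label, c("T(2,0)=4", "T_t(1,1)=4"))
})
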