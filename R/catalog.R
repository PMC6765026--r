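# Closed-form catalog of capsid designs: generalized T-numbers, face censuses,
# dual (Laves) tile counts, protein stoichiometries and size scalings.
#
# With T = h^2 + hk + k^2, the icosahedral census of the design built on
# lattice j is: 12 vertex pentagons, 10(T-1) hexagons, and per-T triangle /
# square coefficients fixed by area bookkeeping (each symmetry vertex retains
# 5/6 of a hexagon) together with Euler's relation; the T = 1 solids are the
# icosahedral Archimedean solids.  Octahedral designs replace 12 pentagonal
# insertions by 6 squares retaining 4/6 of a hexagon.

SYMMETRY_CLASSES <- c("icosahedral", "octahedral")

#' Symmetry class parameters
#'
#' @param name `"icosahedral"` or `"octahedral"`.
#' @return List with `name`, `n_facets` (20 or 8), `n_vertex_insertions`
#'   (12 or 6), `vertex_polygon` (pentagon or square) and
#'   `vertex_wedge_fraction` (5/6 or 4/6 of a hexagon retained at a symmetry
#'   vertex).
#' @export
symmetry_class <- function(name = c("icosahedral", "octahedral")) {
  name <- match.arg(name)
  if (name == "icosahedral")
    list(name = name, n_facets = 20L, n_vertex_insertions = 12L,
         vertex_polygon = "pentagon", vertex_wedge_fraction = 5 / 6)
  else
    list(name = name, n_facets = 8L, n_vertex_insertions = 6L,
         vertex_polygon = "square", vertex_wedge_fraction = 4 / 6)
}

DUAL_TILE_SHAPE <- c(hexagonal = "triangle", trihexagonal = "rhomb",
                     snub_hexagonal = "floret", rhombitrihexagonal = "kite")

# tile conventions: which (lattice, dual) pairings each convention admits
CONVENTIONS <- data.frame(
  convention = c("ck_strict", "trihex_edge_to_edge", "gyrated_trihex",
                 "triangle_trimer", "rhomb_order_2", "rhomb_order_4",
                 "rhomb_order_6", "floret", "kite_protomer"),
  dual = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
  lattice = c(NA, "trihexagonal", "trihexagonal", "hexagonal",
              "trihexagonal", "trihexagonal", "trihexagonal",
              "snub_hexagonal", "rhombitrihexagonal"),
  stringsAsFactors = FALSE)

#' Tile conventions
#'
#' The tiling conventions under which polyhedral faces (or dual tiles) are
#' translated into protein counts.  `ck_strict` is the Caspar-Klug rule that a
#' tile represents as many proteins as its rotational symmetry (pentagon 5,
#' hexagon 6, triangle 3, square 4), applied to any primal lattice;
#' `trihex_edge_to_edge` is its named restriction to the trihexagonal lattice
#' (MCP on pentamers/hexamers, mCP on triangles); `gyrated_trihex` is the
#' non-edge-to-edge trihexagonal variant with a single protein footprint;
#' `triangle_trimer`, `rhomb_order_2/4/6`, `floret` and `kite_protomer` apply
#' to the dual (Laves) tilings.
#'
#' @return Data frame with columns `convention`, `dual` and `lattice`
#'   (NA = any primal lattice).
#' @export
tile_conventions <- function() CONVENTIONS

default_convention <- function(lattice, dual) {
  if (!dual) return("ck_strict")
  switch(lattice,
         hexagonal = "triangle_trimer",
         trihexagonal = "rhomb_order_2",
         snub_hexagonal = "floret",
         rhombitrihexagonal = "kite_protomer")
}

check_convention <- function(convention, lattice, dual) {
  row <- CONVENTIONS[CONVENTIONS$convention == convention, ]
  if (nrow(row) == 0L)
    stop(sprintf("unknown tile convention '%s'; known: %s", convention,
                 paste(CONVENTIONS$convention, collapse = ", ")))
  if (row$dual != dual || (!is.na(row$lattice) && row$lattice != lattice))
    stop(sprintf(
      "tile convention '%s' is incompatible with the %s %s design (requires %s %s)",
      convention, if (dual) "dual" else "primal", lattice,
      if (row$dual) "dual" else "primal",
      if (is.na(row$lattice)) "lattice" else row$lattice))
  invisible(TRUE)
}

#' Capsid design descriptor
#'
#' A design is the coordinate of a blueprint in the catalog: symmetry class,
#' lattice kind, (h,k), primal-vs-dual flag and tile convention.
#'
#' @param lattice lattice kind (full name or alias).
#' @param h,k non-negative integers, not both zero.
#' @param dual logical; use the dual (Laves) tiling.
#' @param symmetry `"icosahedral"` (default) or `"octahedral"`.
#' @param convention tile convention name (see [tile_conventions()]); default
#'   chosen from `lattice` and `dual`.
#' @param chirality `"levo"` or `"dextro"` (snub hexagonal lattice only).
#' @return Object of class `capsid_design`.
#' @export
#' @examples
#' capsid_design("trihexagonal", 3, 0)                      # Basilisk-type
#' capsid_design("trihex", 1, 1, dual = TRUE)               # MS2 rhomb tiling
capsid_design <- function(lattice, h, k, dual = FALSE,
                          symmetry = c("icosahedral", "octahedral"),
                          convention = NULL,
                          chirality = c("levo", "dextro")) {
  lattice <- match_lattice_kind(lattice)
  symmetry <- match.arg(symmetry)
  chirality <- match.arg(chirality)
  hk <- hk_index(h, k)
  if (is.null(convention)) convention <- default_convention(lattice, dual)
  check_convention(convention, lattice, dual)
  structure(list(symmetry = symmetry, lattice = lattice, hk = hk,
                 dual = isTRUE(dual), convention = convention,
                 chirality = chirality),
            class = "capsid_design")
}

#' @export
print.capsid_design <- function(x, ...) {
  cat(sprintf("Capsid design %s: %s %s lattice, (h,k) = (%d,%d), convention %s\n",
              t_label(x$lattice, x$hk[1], x$hk[2], x$dual),
              x$symmetry, if (x$dual) paste(x$lattice, "dual") else x$lattice,
              x$hk[1], x$hk[2], x$convention))
  invisible(x)
}

#' Caspar-Klug triangulation number
#'
#' `T(h,k) = h^2 + h*k + k^2`, the squared hexagon-center distance in units of
#' the (1,0) case.
#'
#' @param h,k non-negative integers, not both zero.
#' @return A positive integer.
#' @export
#' @examples
#' t_number(1, 1)  # 3
#' t_number(2, 1)  # 7
t_number <- function(h, k) {
  hk <- hk_index(h, k)
  as.integer(hk[1]^2 + hk[1] * hk[2] + hk[2]^2)
}

# exact scaled T-number as p/q + (r/s) sqrt(3)
t_scaled_exact <- function(kind, h, k) {
  a <- alpha_exact(kind)
  Tn <- t_number(h, k)
  x <- c(a[1] * Tn, a[2], a[3] * Tn, a[4])
  g1 <- gcd2(x[1], x[2]); g2 <- gcd2(x[3], x[4])
  c(x[1] / max(g1, 1), x[2] / max(g1, 1),
    if (x[3] == 0) c(0, 1) else c(x[3] / g2, x[4] / g2))
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Scaled (generalized) triangulation number
#'
#' `T_j(h,k) = alpha_j * (h^2 + h*k + k^2)` for lattice kind j.  The hexagonal
#' kind returns the classical Caspar-Klug T-number.
#'
#' @inheritParams capsid_design
#' @return A positive number (exact up to floating point; use [t_label()] for
#'   the exact rational rendering).
#' @export
#' @examples
#' t_scaled("trihexagonal", 3, 0)  # 12
#' t_scaled("snub", 1, 1)          # 7
t_scaled <- function(lattice, h, k) {
  surd_value(t_scaled_exact(match_lattice_kind(lattice), h, k))
}

round_half_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

format_surd <- function(x) {
  if (x[3] == 0) {
    if (x[2] == 1) sprintf("%d", as.integer(x[1]))
    else sprintf("%d/%d", as.integer(x[1]), as.integer(x[2]))
  } else {
    sprintf("%.2f", round_half_up(surd_value(x), 2))
  }
}

#' T-number label of a design
#'
#' Renders labels such as `"T(2,1)=7"`, `"T_t(2,1)=28/3"` or
#' `"T_r^D(1,0)=2.49"`.  Exact rationals are printed as fractions; values with
#' a surd part are rounded half-up to two decimals.
#'
#' @inheritParams capsid_design
#' @return Character scalar.
#' @export
t_label <- function(lattice, h, k, dual = FALSE) {
  lattice <- match_lattice_kind(lattice)
  suffix <- switch(lattice, hexagonal = "", trihexagonal = "_t",
                   snub_hexagonal = "_s", rhombitrihexagonal = "_r")
  sprintf("T%s%s(%d,%d)=%s", suffix, if (dual) "^D" else "", h, k,
          format_surd(t_scaled_exact(lattice, h, k)))
}

KIND_INDEX <- c(hexagonal = 1L, trihexagonal = 2L, snub_hexagonal = 3L,
                rhombitrihexagonal = 4L)

#' Closed-form face census of a design
#'
#' Face, vertex and edge counts of the polyhedron underlying a design, together
#' with the dual tile count (= primal vertex count) and dual tile shape.  For
#' icosahedral designs with `T = t_number(h,k)`: 12 vertex pentagons,
#' `10(T-1)` hexagons, `{0, 20, 80, 20} T` triangles and `{0, 0, 0, 30} T`
#' squares for the hexagonal, trihexagonal, snub and rhombitrihexagonal
#' lattices; `V = {20, 30, 60, 60} T`.  Octahedral designs: 6 vertex squares,
#' `4(T-1)` hexagons, `{0, 8, 32, 8} T` triangles, `{0, 0, 0, 12} T` squares,
#' `V = {8, 12, 24, 24} T`.
#'
#' @param design a [capsid_design()].
#' @return Object of class `face_census`: list with counts `vertex_polygons`,
#'   `hexagons`, `triangles`, `squares`, `dual_tiles`, `tile_shape`, and `V`,
#'   `E`, `F`.
#' @export
#' @examples
#' face_census(capsid_design("trihexagonal", 3, 0))
face_census <- function(design) {
  stopifnot(inherits(design, "capsid_design"))
  Tn <- t_number(design$hk[1], design$hk[2])
  i <- KIND_INDEX[design$lattice]
  if (design$symmetry == "icosahedral") {
    vp <- 12L; hexagons <- 10L * (Tn - 1L)
    triangles <- c(0L, 20L, 80L, 20L)[i] * Tn
    squares <- c(0L, 0L, 0L, 30L)[i] * Tn
    V <- c(20L, 30L, 60L, 60L)[i] * Tn
  } else {
    vp <- 6L; hexagons <- 4L * (Tn - 1L)
    triangles <- c(0L, 8L, 32L, 8L)[i] * Tn
    squares <- c(0L, 0L, 0L, 12L)[i] * Tn
    V <- c(8L, 12L, 24L, 24L)[i] * Tn
  }
  F <- vp + hexagons + triangles + squares
  E <- V + F - 2L
  structure(list(vertex_polygons = vp, hexagons = hexagons,
                 triangles = triangles, squares = squares,
                 dual_tiles = V, tile_shape = unname(DUAL_TILE_SHAPE[design$lattice]),
                 V = V, E = E, F = F),
            class = "face_census")
}

#' @export
print.face_census <- function(x, ...) {
  cat(sprintf(
    "Face census: %d vertex polygons, %d hexagons, %d triangles, %d squares\n",
    x$vertex_polygons, x$hexagons, x$triangles, x$squares))
  cat(sprintf("  V = %d, E = %d, F = %d; dual: %d %s tiles\n",
              x$V, x$E, x$F, x$dual_tiles, x$tile_shape))
  invisible(x)
}

#' Protein stoichiometry of a design
#'
#' Translates the face census of a design into major/minor capsid protein
#' (MCP/mCP) counts under the design's tile convention.  Under the strict
#' Caspar-Klug rule a tile carries as many proteins as its rotational
#' symmetry: pentagons 5, hexagons 6, triangles 3, squares 4 (octahedral
#' vertex squares 4).  Dual tilings carry per-tile counts: 3 per triangle,
#' 2/4/6 per rhomb for rhomb orders 2/4/6, 3 domains per kite, and a
#' configurable count per floret tile.
#'
#' @param design a [capsid_design()].
#' @param n_per_tile proteins per floret tile (used by the `floret`
#'   convention only; the symmetry rule is relaxed there, so the count is a
#'   parameter, default 6).
#' @return Object of class `stoichiometry`: list with `n_MCP`, `n_mCP`,
#'   `n_total`, `breakdown` (data frame: `unit`, `multiplicity`,
#'   `proteins_each`), `hypothetical` flag and the design label.
#' @export
#' @examples
#' stoichiometry(capsid_design("trihexagonal", 3, 0))  # 540 MCP + 540 mCP
stoichiometry <- function(design, n_per_tile = 6) {
  stopifnot(inherits(design, "capsid_design"))
  cen <- face_census(design)
  conv <- design$convention
  vp_proteins <- if (design$symmetry == "icosahedral") 5L else 4L
  vp_name <- if (design$symmetry == "icosahedral") "pentamer" else "vertex tetramer"
  hypothetical <- FALSE
  if (!design$dual) {
    if (conv == "gyrated_trihex") {
      # single-footprint gyrated tiling: MCP/mCP distinction dropped
      bd <- data.frame(
        unit = c(vp_name, "hexamer", "trimer"),
        multiplicity = c(cen$vertex_polygons, cen$hexagons, cen$triangles),
        proteins_each = c(vp_proteins, 6L, 3L))
      n_total <- sum(bd$multiplicity * bd$proteins_each)
      n_MCP <- n_total; n_mCP <- 0L
    } else {
      bd <- data.frame(
        unit = c(vp_name, "hexamer", "trimer", "tetramer (square)"),
        multiplicity = c(cen$vertex_polygons, cen$hexagons, cen$triangles,
                         cen$squares),
        proteins_each = c(vp_proteins, 6L, 3L, 4L))
      bd <- bd[bd$multiplicity > 0L, , drop = FALSE]
      n_MCP <- cen$vertex_polygons * vp_proteins + cen$hexagons * 6L
      n_mCP <- cen$triangles * 3L + cen$squares * 4L
      n_total <- n_MCP + n_mCP
      # no capsid examples are known for the regular snub hexagonal and
      # rhombitrihexagonal primal lattices
      hypothetical <- design$lattice %in%
        c("snub_hexagonal", "rhombitrihexagonal")
    }
  } else {
    per_tile <- switch(conv,
                       triangle_trimer = 3L,
                       rhomb_order_2 = 2L,
                       rhomb_order_4 = 4L,
                       rhomb_order_6 = 6L,
                       kite_protomer = 3L,
                       floret = as.integer(n_per_tile))
    unit <- switch(conv,
                   triangle_trimer = "triangle tile (trimer)",
                   rhomb_order_2 = "rhomb tile (1 dimer)",
                   rhomb_order_4 = "rhomb tile (2 dimers)",
                   rhomb_order_6 = "rhomb tile (3 dimers)",
                   kite_protomer = "kite tile (3-domain protomer)",
                   floret = sprintf("floret tile (%d proteins)", per_tile))
    bd <- data.frame(unit = unit, multiplicity = cen$dual_tiles,
                     proteins_each = per_tile)
    n_total <- cen$dual_tiles * per_tile
    n_MCP <- n_total; n_mCP <- 0L
  }
  structure(list(n_MCP = as.integer(n_MCP), n_mCP = as.integer(n_mCP),
                 n_total = as.integer(n_total), breakdown = bd,
                 convention = conv, hypothetical = hypothetical,
                 label = t_label(design$lattice, design$hk[1], design$hk[2],
                                 design$dual)),
            class = "stoichiometry")
}

#' @export
print.stoichiometry <- function(x, ...) {
  cat(sprintf("Stoichiometry for %s (%s): %d proteins (%d MCP + %d mCP)%s\n",
              x$label, x$convention, x$n_total, x$n_MCP, x$n_mCP,
              if (x$hypothetical) " [hypothetical: no known virus]" else ""))
  print(x$breakdown, row.names = FALSE)
  invisible(x)
}

#' Relative size of two capsid designs
#'
#' Assuming equal per-protein footprints, the surface areas of two designs are
#' in the ratio `(alpha_a * T_a) / (alpha_b * T_b)`; radii scale as the square
#' root of that ratio and volumes as its 3/2 power.
#'
#' @param design_a,design_b two [capsid_design()] objects.
#' @return Object of class `size_scaling`: list with `area_ratio`,
#'   `radius_ratio` and `volume_ratio`.
#' @export
#' @examples
#' # trihexagonal vs classical (2,1): volume factor (4/3)^(3/2) ~ 1.54
#' size_scaling(capsid_design("trihex", 2, 1), capsid_design("hex", 2, 1))
size_scaling <- function(design_a, design_b) {
  stopifnot(inherits(design_a, "capsid_design"),
            inherits(design_b, "capsid_design"))
  area_ratio <- (alpha_factor(design_a$lattice) *
                   t_number(design_a$hk[1], design_a$hk[2])) /
    (alpha_factor(design_b$lattice) * t_number(design_b$hk[1], design_b$hk[2]))
  structure(list(area_ratio = area_ratio,
                 radius_ratio = sqrt(area_ratio),
                 volume_ratio = area_ratio^1.5),
            class = "size_scaling")
}

#' @export
print.size_scaling <- function(x, ...) {
  cat(sprintf("area ratio %.6f, radius ratio %.6f, volume ratio %.6f\n",
              x$area_ratio, x$radius_ratio, x$volume_ratio))
  invisible(x)
}

#' Enumerate the design catalog
#'
#' One row per (symmetry, lattice, h, k, dual, convention) combination with
#' scaled T-number at most `max_T`, with census, stoichiometry and label
#' columns, sorted by scaled T-number.
#'
#' @param max_T upper bound (inclusive) on the scaled T-number `alpha_j * T`.
#' @param symmetry character vector of symmetry classes to include.
#' @param kinds character vector of lattice kinds (full names or aliases).
#' @param include_dual include dual (Laves) designs.
#' @param conventions restrict to these tile conventions (default: all
#'   compatible conventions).
#' @param n_per_tile proteins per floret tile.
#' @return A data frame of catalog rows.
#' @export
#' @examples
#' enumerate_designs(4, kinds = "trihexagonal")
enumerate_designs <- function(max_T, symmetry = "icosahedral",
                              kinds = LATTICE_KINDS, include_dual = TRUE,
                              conventions = NULL, n_per_tile = 6) {
  if (!is.numeric(max_T) || max_T < 1) stop("max_T must be >= 1")
  symmetry <- vapply(symmetry, function(s)
    match.arg(s, SYMMETRY_CLASSES), character(1))
  kinds <- vapply(kinds, match_lattice_kind, character(1))
  if (is.null(conventions)) conventions <- CONVENTIONS$convention
  rows <- list()
  for (sym in symmetry) for (kind in kinds) {
    alpha <- alpha_factor(kind)
    Tmax <- floor(max_T / alpha + 1e-9)
    if (Tmax < 1) next
    hmax <- floor(sqrt(Tmax))
    for (h in 1:hmax) for (k in 0:h) {
      Tn <- h^2 + h * k + k^2
      if (Tn > Tmax) next
      for (dual in c(FALSE, TRUE)) {
        if (dual && !include_dual) next
        ok <- CONVENTIONS$convention[CONVENTIONS$dual == dual &
          (is.na(CONVENTIONS$lattice) | CONVENTIONS$lattice == kind)]
        ok <- intersect(ok, conventions)
        for (conv in ok) {
          d <- capsid_design(kind, h, k, dual = dual, symmetry = sym,
                             convention = conv)
          cen <- face_census(d)
          st <- stoichiometry(d, n_per_tile = n_per_tile)
          rows[[length(rows) + 1L]] <- data.frame(
            symmetry = sym, lattice = kind, h = h, k = k, T = Tn,
            T_scaled = alpha * Tn,
            T_label = t_label(kind, h, k, dual),
            dual = dual, convention = conv,
            vertex_polygons = cen$vertex_polygons, hexagons = cen$hexagons,
            triangles = cen$triangles, squares = cen$squares,
            dual_tiles = cen$dual_tiles, tile_shape = cen$tile_shape,
            n_MCP = st$n_MCP, n_mCP = st$n_mCP, n_total = st$n_total,
            V = cen$V, E = cen$E, F = cen$F,
            hypothetical = st$hypothetical,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(invisible(data.frame()))
  cat_df <- do.call(rbind, rows)
  ord <- order(cat_df$T_scaled, match(cat_df$lattice, LATTICE_KINDS),
               cat_df$dual, match(cat_df$symmetry, SYMMETRY_CLASSES),
               match(cat_df$convention, CONVENTIONS$convention))
  cat_df <- cat_df[ord, , drop = FALSE]
  rownames(cat_df) <- NULL
  cat_df
}
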