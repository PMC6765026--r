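# Planar geometry of the four Archimedean lattices with a hexagonal sublattice.
#
# All coordinates are 2D Cartesian with lattice polygon edge length 1.  The
# hexagonal sublattice (the hexagon centers) is spanned by a1 = (s, 0) and
# a2 = rot60(a1) = (s/2, s*sqrt(3)/2), where s is the hexagon-center spacing.
# The (h,k) facet triangle is (origin, C, rot60(C)) with C = h*a1 + k*a2.

LATTICE_KINDS <- c("hexagonal", "trihexagonal", "snub_hexagonal",
                   "rhombitrihexagonal")

VERTEX_SYMBOLS <- c(hexagonal = "(6,6,6)",
                    trihexagonal = "(3,6,3,6)",
                    snub_hexagonal = "(3^4,6)",
                    rhombitrihexagonal = "(3,4,6,4)")

LATTICE_ALIASES <- c(hex = "hexagonal", hexagonal = "hexagonal",
                     trihex = "trihexagonal", trihexagonal = "trihexagonal",
                     snub = "snub_hexagonal", snub_hexagonal = "snub_hexagonal",
                     rhombi = "rhombitrihexagonal",
                     rhombitrihexagonal = "rhombitrihexagonal")

#' The four admissible lattice kinds
#'
#' The Archimedean (uniform) plane tilings that contain a hexagonal
#' sublattice and therefore admit the Caspar-Klug pentagon-insertion
#' construction.
#'
#' @return Character vector of the four kind names.
#' @export
lattice_kinds <- function() LATTICE_KINDS

#' Canonicalize a lattice kind name
#'
#' Accepts the full names `hexagonal`, `trihexagonal`, `snub_hexagonal`,
#' `rhombitrihexagonal` or the short aliases `hex`, `trihex`, `snub`, `rhombi`.
#'
#' @param kind character scalar naming an Archimedean lattice with a hexagonal
#'   sublattice.
#' @return The canonical kind name.
#' @export
match_lattice_kind <- function(kind) {
  if (!is.character(kind) || length(kind) != 1L || is.na(kind))
    stop("lattice kind must be a single character string")
  full <- unname(LATTICE_ALIASES[kind])
  if (is.na(full))
    stop(sprintf(
      "unknown lattice kind '%s'; expected one of %s (or aliases hex, trihex, snub, rhombi)",
      kind, paste(LATTICE_KINDS, collapse = ", ")))
  full
}

# exact alpha as p/q + (r/s)*sqrt(3)
alpha_exact <- function(kind) {
  kind <- match_lattice_kind(kind)
  switch(kind,
         hexagonal          = c(1, 1, 0, 1),
         trihexagonal       = c(4, 3, 0, 1),
         snub_hexagonal     = c(7, 3, 0, 1),
         rhombitrihexagonal = c(4, 3, 2, 3))  # 4/3 + 2/sqrt(3) = 4/3 + (2/3)sqrt(3)
}

surd_value <- function(x) x[1] / x[2] + x[3] / x[4] * sqrt(3)

#' Lattice area scaling factor alpha
#'
#' Ratio of the area of the (1,0) facet triangle of a lattice to that of the
#' hexagonal lattice at equal polygon edge length: 1 (hexagonal), 4/3
#' (trihexagonal), 7/3 (snub hexagonal) and 4/3 + 2/sqrt(3) ~ 2.49
#' (rhombitrihexagonal).
#'
#' @inheritParams match_lattice_kind
#' @return A positive number.
#' @export
#' @examples
#' alpha_factor("trihexagonal")  # 4/3
alpha_factor <- function(kind) surd_value(alpha_exact(kind))

hex_center_spacing <- function(kind) {
  switch(match_lattice_kind(kind),
         hexagonal          = sqrt(3),
         trihexagonal       = 2,
         snub_hexagonal     = sqrt(7),
         rhombitrihexagonal = 1 + sqrt(3))
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}
ROT60 <- rot2(pi / 3)

#' Geometric specification of a lattice
#'
#' Returns the hexagon-center spacing, the hexagonal-sublattice basis and the
#' vertex symbol for one of the four admissible Archimedean lattices, at
#' polygon edge length 1.
#'
#' @inheritParams match_lattice_kind
#' @param chirality `"levo"` or `"dextro"`; only the snub hexagonal lattice is
#'   chiral, for the other kinds both values give identical geometry.
#' @return An object of class `lattice_spec`: a list with elements `kind`,
#'   `chirality`, `vertex_symbol`, `edge_length`, `hex_center_spacing` and
#'   `basis` (2x2 matrix with columns a1, a2).
#' @export
lattice_spec <- function(kind, chirality = c("levo", "dextro")) {
  kind <- match_lattice_kind(kind)
  chirality <- match.arg(chirality)
  s <- hex_center_spacing(kind)
  basis <- cbind(a1 = c(s, 0), a2 = c(s / 2, s * sqrt(3) / 2))
  structure(list(kind = kind, chirality = chirality,
                 vertex_symbol = unname(VERTEX_SYMBOLS[kind]),
                 edge_length = 1, hex_center_spacing = s, basis = basis),
            class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("Archimedean lattice %s %s\n", x$kind, x$vertex_symbol))
  cat(sprintf("  edge length 1, hexagon-center spacing %.6f (alpha = %.6f)\n",
              x$hex_center_spacing, x$hex_center_spacing^2 / 3))
  if (x$kind == "snub_hexagonal")
    cat(sprintf("  chirality: %s\n", x$chirality))
  invisible(x)
}

#' Validate (h,k) lattice indices
#'
#' @param h,k non-negative integers, not both zero.
#' @return Integer vector c(h, k).
#' @export
hk_index <- function(h, k) {
  if (length(h) != 1L || length(k) != 1L || is.na(h) || is.na(k) ||
      h != round(h) || k != round(k) || h < 0 || k < 0 || (h == 0 && k == 0))
    stop("(h,k) must be non-negative integers, not both zero")
  c(h = as.integer(h), k = as.integer(k))
}

# unit offsets from a hexagon center to its 6 vertices, counter-clockwise
hex_vertex_offsets <- function(kind, chirality = "levo") {
  kind <- match_lattice_kind(kind)
  ang0 <- switch(kind,
                 hexagonal = pi / 6,
                 trihexagonal = 0,
                 rhombitrihexagonal = pi / 6,
                 snub_hexagonal = -atan2(sqrt(3) / 2, 2.5))
  ang <- ang0 + pi / 3 * (0:5)
  off <- cbind(cos(ang), sin(ang))
  if (kind == "snub_hexagonal" && chirality == "dextro") {
    off[, 2] <- -off[, 2]
    off <- off[c(1L, 6:2), , drop = FALSE]  # keep counter-clockwise order
  }
  off
}

# signed area (shoelace); positive for counter-clockwise polygons
polygon_area <- function(verts) {
  x <- verts[, 1]; y <- verts[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

# normalize polygon winding to counter-clockwise
ccw <- function(verts) {
  if (polygon_area(verts) < 0) verts[rev(seq_len(nrow(verts))), , drop = FALSE]
  else verts
}

# Enumerate the lattice faces whose centroid falls inside a bounding box.
# Returns a list of faces, each list(class, center, verts) with verts a k x 2
# counter-clockwise matrix.  Each face is emitted exactly once.
lattice_faces <- function(kind, xlim, ylim, chirality = "levo") {
  kind <- match_lattice_kind(kind)
  s <- hex_center_spacing(kind)
  a1 <- c(s, 0); a2 <- c(s / 2, s * sqrt(3) / 2)
  faces <- list()
  nf <- 0L
  add <- function(class, verts, center) {
    if (center[1] < xlim[1] || center[1] > xlim[2] ||
        center[2] < ylim[1] || center[2] > ylim[2]) return(invisible())
    nf <<- nf + 1L
    faces[[nf]] <<- list(class = class, center = center, verts = ccw(verts))
    invisible()
  }
  index_range <- function(b1, b2, margin) {
    corners <- rbind(c(xlim[1], ylim[1]), c(xlim[2], ylim[1]),
                     c(xlim[1], ylim[2]), c(xlim[2], ylim[2]))
    mn <- t(solve(cbind(b1, b2)) %*% t(corners))
    list(m = floor(min(mn[, 1]) - margin):ceiling(max(mn[, 1]) + margin),
         n = floor(min(mn[, 2]) - margin):ceiling(max(mn[, 2]) + margin))
  }
  hexoff <- hex_vertex_offsets(kind, chirality)

  if (kind == "snub_hexagonal") {
    # underlying unit triangular lattice; hexagons merge the six triangles
    # around each vertex of the index-7 sublattice (3i + j = 0 mod 7)
    theta <- atan2(sqrt(3) / 2, 2.5)
    R <- rot2(-theta)
    b1 <- drop(R %*% c(1, 0)); b2 <- drop(R %*% c(0.5, sqrt(3) / 2))
    if (chirality == "dextro") { b1[2] <- -b1[2]; b2[2] <- -b2[2] }
    in_H <- function(i, j) (3L * i + j) %% 7L == 0L
    rg <- index_range(b1, b2, 2)
    for (i in rg$m) for (j in rg$n) {
      p <- i * b1 + j * b2
      if (in_H(i, j)) add("hexagon", sweep(hexoff, 2, p, "+"), p)
      # up triangle {p, p+b1, p+b2}: part of a hexagon iff a vertex is in H
      if (!in_H(i, j) && !in_H(i + 1L, j) && !in_H(i, j + 1L)) {
        v <- rbind(p, p + b1, p + b2)
        add("triangle", v, colMeans(v))
      }
      # down triangle {p+b1, p+b2, p+b1+b2}
      if (!in_H(i + 1L, j) && !in_H(i, j + 1L) && !in_H(i + 1L, j + 1L)) {
        v <- rbind(p + b1, p + b1 + b2, p + b2)
        add("triangle", v, colMeans(v))
      }
    }
    return(faces)
  }

  rg <- index_range(a1, a2, 2)
  for (m in rg$m) for (n in rg$n) {
    cen <- m * a1 + n * a2
    add("hexagon", sweep(hexoff, 2, cen, "+"), cen)
    if (kind == "trihexagonal") {
      # medial triangles of the up and down sublattice triangles
      up <- rbind(cen + a1 / 2, cen + (a1 + a2) / 2, cen + a2 / 2)
      dn <- rbind(cen + (a1 + a2) / 2, cen + a1 + a2 / 2, cen + a1 / 2 + a2)
      add("triangle", up, colMeans(up))
      add("triangle", dn, colMeans(dn))
    } else if (kind == "rhombitrihexagonal") {
      for (d in list(a1, a2, a2 - a1)) {
        u <- d / sqrt(sum(d^2)); v <- c(-u[2], u[1])
        h0 <- sqrt(3) / 2
        sq <- rbind(cen + h0 * u - v / 2, cen + (h0 + 1) * u - v / 2,
                    cen + (h0 + 1) * u + v / 2, cen + h0 * u + v / 2)
        add("square", sq, cen + d / 2)
      }
      for (corners in list(rbind(cen, cen + a1, cen + a2),
                           rbind(cen + a1, cen + a1 + a2, cen + a2))) {
        g <- colMeans(corners)
        tri <- t(apply(corners, 1, function(p) p + (g - p) / sqrt(sum((g - p)^2))))
        add("triangle", tri, g)
      }
    }
  }
  faces
}

# signed distance of p from directed edge (q0 -> q1); positive to the left,
# i.e. positive inside a counter-clockwise triangle
edge_signed_distance <- function(p, q0, q1) {
  e <- q1 - q0
  ((e[1]) * (p[2] - q0[2]) - (e[2]) * (p[1] - q0[1])) / sqrt(sum(e^2))
}

# classify a point against the facet triangle (q0, q1, q2), counter-clockwise.
# Returns list(loc = interior|edge|corner|outside, which = edge or corner id).
classify_point <- function(p, tri, tol) {
  dc <- sqrt(colSums((t(tri) - p)^2))
  if (any(dc <= tol)) return(list(loc = "corner", which = which.min(dc)))
  d <- c(edge_signed_distance(p, tri[1, ], tri[2, ]),
         edge_signed_distance(p, tri[2, ], tri[3, ]),
         edge_signed_distance(p, tri[3, ], tri[1, ]))
  on_edge <- abs(d) <= tol
  if (any(d < -tol)) return(list(loc = "outside", which = which.min(d)))
  if (any(on_edge)) return(list(loc = "edge", which = which(on_edge)[1]))
  list(loc = "interior", which = 0L)
}

# area of the hexagonal-lattice (1,0) facet triangle at edge length 1
A0_HEX <- 3 * sqrt(3) / 4

#' Planar (h,k) facet patch of a lattice
#'
#' Computes the lattice faces covered by the equilateral facet triangle with
#' corners at the hexagon centers (0,0), C(h,k) and rot60(C(h,k)).  Faces are
#' classified by the position of their centroid: `interior` faces count fully,
#' `edge` faces (centroid exactly on a facet edge) count 1/2, and the three
#' `corner` hexagons count as 1/6 wedges.
#'
#' @inheritParams lattice_spec
#' @param h,k non-negative integers, not both zero.
#' @return An object of class `planar_patch`: list with `kind`, `hk`,
#'   `facet_vertices` (3x2), `entries` (data frame with columns `class`,
#'   `location`, `fraction`, `area`) and `verts` (list of vertex matrices).
#' @export
#' @examples
#' p <- generate_patch("trihexagonal", 1, 0)
#' table(p$entries$class, p$entries$location)
generate_patch <- function(kind, h, k, chirality = c("levo", "dextro")) {
  kind <- match_lattice_kind(kind)
  chirality <- match.arg(chirality)
  hk <- hk_index(h, k)
  spec <- lattice_spec(kind, chirality)
  C <- drop(spec$basis %*% hk)
  tri <- rbind(c(0, 0), C, drop(ROT60 %*% C))
  tol <- 1e-9 * spec$hex_center_spacing
  margin <- 2.5
  fl <- lattice_faces(kind, range(tri[, 1]) + c(-margin, margin),
                      range(tri[, 2]) + c(-margin, margin), chirality)
  cls <- character(0); loc <- character(0); frac <- numeric(0)
  area <- numeric(0); verts <- list()
  for (f in fl) {
    cl <- classify_point(f$center, tri, tol)
    if (cl$loc == "outside") next
    fr <- switch(cl$loc, interior = 1, edge = 0.5, corner = 1 / 6)
    if (cl$loc == "corner" && f$class != "hexagon")
      stop("internal error: corner face is not a hexagon")
    cls <- c(cls, f$class); loc <- c(loc, cl$loc); frac <- c(frac, fr)
    area <- c(area, polygon_area(f$verts))
    verts[[length(verts) + 1L]] <- f$verts
  }
  structure(list(kind = kind, hk = hk, chirality = chirality,
                 facet_vertices = tri,
                 entries = data.frame(class = cls, location = loc,
                                      fraction = frac, area = area),
                 verts = verts),
            class = "planar_patch")
}

#' Fractional area of a planar patch
#'
#' Sum of wedge-fraction times polygon area over the patch entries; equals
#' `alpha_factor(kind) * (h^2 + h*k + k^2) * A0` with `A0 = 3*sqrt(3)/4`, the
#' area of the hexagonal (1,0) facet triangle at equal edge length.
#'
#' @param patch a `planar_patch`.
#' @return A positive number (squared edge units).
#' @export
patch_area <- function(patch) {
  stopifnot(inherits(patch, "planar_patch"))
  sum(patch$entries$fraction * patch$entries$area)
}

#' @export
print.planar_patch <- function(x, ...) {
  cat(sprintf("Planar patch: %s lattice, (h,k) = (%d,%d)\n",
              x$kind, x$hk[1], x$hk[2]))
  print(stats::aggregate(fraction ~ class + location, data = x$entries, FUN = sum))
  cat(sprintf("fractional area %.6f = alpha * T * A0 = %.6f\n",
              patch_area(x),
              alpha_factor(x$kind) * sum(x$hk[1]^2 + x$hk[1] * x$hk[2] + x$hk[2]^2) * A0_HEX))
  invisible(x)
}
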