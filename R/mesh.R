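# Explicit 3D polyhedral meshes: fold the planar (h,k) lattice embedding onto
# an icosahedron or octahedron, weld shared boundaries, build duals, measure.
#
# No polygon clipping is performed.  Every lattice face is assigned to the
# facet containing its centroid and mapped by that facet's isometry, extended
# across each facet edge by the fold onto the neighboring facet plane.  This
# is exact because all four lattices have a 2-fold rotation point at the
# midpoint between adjacent hexagon centers (the facet edge midpoint) and a
# 3-fold point at the facet centroid, so the lattice overlays of adjacent
# facets agree along shared edges.  Faces whose centroid lies exactly on a
# fold edge are generated from both adjacent facets and deduplicated after
# vertex welding.  The hexagons centered at the symmetry vertices are replaced
# by pentagons (icosahedral) or squares (octahedral) assembled from the
# retained 60-degree wedges of the incident facets.

# vertices and counter-clockwise (outward) triangular faces of the base solid
base_solid <- function(symmetry = c("icosahedral", "octahedral"), edge = 1) {
  symmetry <- match.arg(symmetry)
  if (symmetry == "icosahedral") {
    phi <- (1 + sqrt(5)) / 2
    v <- rbind(
      c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi),
      c(1, phi, 0), c(1, -phi, 0), c(-1, phi, 0), c(-1, -phi, 0),
      c(phi, 0, 1), c(phi, 0, -1), c(-phi, 0, 1), c(-phi, 0, -1))
    v <- v * (edge / 2)
    raw_edge <- edge
  } else {
    v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
    v <- v * (edge / sqrt(2))
    raw_edge <- edge
  }
  n <- nrow(v)
  d <- as.matrix(stats::dist(v))
  faces <- list()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    if (abs(d[i, j] - raw_edge) < 1e-9 * raw_edge &&
        abs(d[i, k] - raw_edge) < 1e-9 * raw_edge &&
        abs(d[j, k] - raw_edge) < 1e-9 * raw_edge) {
      f <- c(i, j, k)
      nrm <- crossprod3(v[j, ] - v[i, ], v[k, ] - v[i, ])
      if (sum(nrm * (v[i, ] + v[j, ] + v[k, ])) < 0) f <- c(i, k, j)
      faces[[length(faces) + 1L]] <- f
    }
  }
  list(vertices = v, faces = faces, symmetry = symmetry, edge = edge)
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# isometric affine map from 3 planar points to 3 matching 3D points;
# returns a function mapping an n x 2 matrix to an n x 3 matrix
iso_map <- function(src, dst) {
  S <- cbind(src[2, ] - src[1, ], src[3, ] - src[1, ])
  E <- cbind(dst[2, ] - dst[1, ], dst[3, ] - dst[1, ])
  M <- E %*% solve(S)
  s0 <- src[1, ]; d0 <- dst[1, ]
  function(p) {
    p <- matrix(p, ncol = 2)
    sweep(t(M %*% t(sweep(p, 2, s0))), 2, d0, "+")
  }
}

reflect_point <- function(p, q0, q1) {
  e <- q1 - q0; e <- e / sqrt(sum(e^2))
  d <- p - q0
  q0 + 2 * sum(d * e) * e - d
}

#' Build the 3D polyhedral mesh of a capsid design
#'
#' Folds the planar (h,k) lattice embedding onto the facets of an icosahedron
#' (or octahedron), welding shared boundaries.  Hexagons centered at the
#' symmetry vertices become pentagons (squares for octahedral symmetry) by
#' wedge removal.  For dual designs the primal mesh is built first and
#' [build_dual()] applied.  The mesh scale is lattice edge = 1; faces that
#' straddle fold edges are kept as single (bent) cycles.
#'
#' @param design a [capsid_design()].
#' @param project_to_sphere radially normalize vertices to the mean radius.
#' @param mirror return the mirror-image enantiomorph.
#' @param weld_tolerance vertex welding tolerance, relative to the lattice
#'   edge.
#' @return Object of class `capsid_mesh`: list with `vertices` (n x 3 matrix),
#'   `faces` (list of vertex index cycles, counter-clockwise from outside),
#'   `labels` (face class per face) and `design`.
#' @export
#' @examples
#' m <- build_polyhedron(capsid_design("hexagonal", 1, 1))
#' mesh_census(m)  # truncated icosahedron: 12 pentagons, 20 hexagons
build_polyhedron <- function(design, project_to_sphere = FALSE,
                             mirror = FALSE, weld_tolerance = 1e-6) {
  stopifnot(inherits(design, "capsid_design"))
  if (design$dual) {
    primal <- design
    primal$dual <- FALSE
    primal$convention <- default_convention(design$lattice, FALSE)
    m <- build_polyhedron(primal, project_to_sphere = project_to_sphere,
                          mirror = mirror, weld_tolerance = weld_tolerance)
    return(build_dual(m))
  }
  kind <- design$lattice
  h <- design$hk[1]; k <- design$hk[2]
  spec <- lattice_spec(kind, design$chirality)
  s <- spec$hex_center_spacing
  C <- drop(spec$basis %*% c(h, k))
  L <- sqrt(sum(C^2))
  tri <- rbind(c(0, 0), C, drop(ROT60 %*% C))
  tol <- 1e-9 * s

  solid <- base_solid(design$symmetry, edge = L)
  nfac <- length(solid$faces)

  # directed edge (a,b) -> facet index
  dmap <- new.env(hash = TRUE, parent = emptyenv())
  for (fi in seq_len(nfac)) {
    f <- solid$faces[[fi]]
    for (e in 1:3)
      assign(paste(f[e], f[e %% 3 + 1]), fi, envir = dmap)
  }

  margin <- 2.5
  fl <- lattice_faces(kind, range(tri[, 1]) + c(-margin, margin),
                      range(tri[, 2]) + c(-margin, margin), design$chirality)
  keep <- list(); nkeep <- 0L
  for (f in fl) {
    cl <- classify_point(f$center, tri, tol)
    if (cl$loc %in% c("interior", "edge")) {
      nkeep <- nkeep + 1L
      keep[[nkeep]] <- f
    }
  }

  # per-facet isometries and single-fold extensions
  hexoff <- hex_vertex_offsets(kind, design$chirality)
  edge_pairs <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  maps <- vector("list", nfac)
  for (fi in seq_len(nfac)) {
    fv <- solid$faces[[fi]]
    dst <- solid$vertices[fv, , drop = FALSE]
    main <- iso_map(tri, dst)
    folds <- vector("list", 3L)
    for (e in 1:3) {
      i1 <- edge_pairs[e, 1]; i2 <- edge_pairs[e, 2]
      gi <- get(paste(fv[i2], fv[i1]), envir = dmap)  # neighbor facet
      gv <- solid$faces[[gi]]
      w <- setdiff(gv, fv[c(i1, i2)])
      src_f <- rbind(tri[i1, ], tri[i2, ],
                     reflect_point(tri[setdiff(1:3, c(i1, i2)), ],
                                   tri[i1, ], tri[i2, ]))
      dst_f <- rbind(dst[i1, ], dst[i2, ],
                     solid$vertices[w, , drop = FALSE])
      folds[[e]] <- iso_map(src_f, dst_f)
    }
    maps[[fi]] <- list(main = main, folds = folds)
  }

  # classify each kept face's vertices once: 0 = inside the facet triangle
  # (main map), 1..3 = beyond that fold edge
  for (i in seq_along(keep)) {
    verts <- keep[[i]]$verts
    d <- cbind(
      apply(verts, 1, edge_signed_distance, q0 = tri[1, ], q1 = tri[2, ]),
      apply(verts, 1, edge_signed_distance, q0 = tri[2, ], q1 = tri[3, ]),
      apply(verts, 1, edge_signed_distance, q0 = tri[3, ], q1 = tri[1, ]))
    region <- integer(nrow(verts))
    for (r in seq_len(nrow(verts))) {
      neg <- which(d[r, ] < -tol)
      if (length(neg) > 1L)
        stop("weld failure: lattice vertex falls in the removed wedge region ",
             "around a symmetry vertex")
      region[r] <- if (length(neg) == 0L) 0L else neg
    }
    keep[[i]]$region <- region
  }

  map_vertices <- function(fi, verts, region) {
    out <- matrix(0, nrow(verts), 3)
    inside <- region == 0L
    if (any(inside))
      out[inside, ] <- maps[[fi]]$main(verts[inside, , drop = FALSE])
    for (e in 1:3) {
      sel <- region == e
      if (any(sel))
        out[sel, ] <- maps[[fi]]$folds[[e]](verts[sel, , drop = FALSE])
    }
    out
  }

  coords <- list(); fcycles <- list(); flabels <- character(0)
  push_face <- function(xyz, label) {
    coords[[length(coords) + 1L]] <<- xyz
    fcycles[[length(fcycles) + 1L]] <<- nrow(xyz)
    flabels[[length(flabels) + 1L]] <<- label
  }

  for (fi in seq_len(nfac)) {
    for (f in keep)
      push_face(map_vertices(fi, f$verts, f$region), f$class)
  }

  # vertex polygons: walk the facets around each symmetry vertex and collect
  # the retained wedge vertices of the corner hexagons
  atol <- 1e-9
  vp_label <- "vertex_polygon"
  for (vi in seq_len(nrow(solid$vertices))) {
    f0 <- NULL
    for (fi in seq_len(nfac)) if (vi %in% solid$faces[[fi]]) { f0 <- fi; break }
    walk <- integer(0); fi <- f0
    repeat {
      walk <- c(walk, fi)
      fv <- solid$faces[[fi]]
      pos <- match(vi, fv)
      pred <- fv[(pos + 1L) %% 3L + 1L]  # previous vertex in the cycle
      fi <- get(paste(vi, pred), envir = dmap)
      if (fi == f0) break
    }
    pts <- NULL
    for (fi in walk) {
      fv <- solid$faces[[fi]]
      pos <- match(vi, fv)
      q_c <- tri[pos, ]
      q_next <- tri[pos %% 3L + 1L, ]
      dir0 <- q_next - q_c
      ang <- apply(hexoff, 1, function(o)
        atan2(dir0[1] * o[2] - dir0[2] * o[1], dir0[1] * o[1] + dir0[2] * o[2]))
      ang <- ang %% (2 * pi)
      ang[ang >= 2 * pi - atol] <- ang[ang >= 2 * pi - atol] - 2 * pi
      sel <- which(ang <= pi / 3 + atol)
      sel <- sel[order(ang[sel])]
      wedge <- sweep(hexoff[sel, , drop = FALSE], 2, q_c, "+")
      pts <- rbind(pts, maps[[fi]]$main(wedge))
    }
    push_face(pts, vp_label)
  }

  # weld coincident vertices
  all_xyz <- do.call(rbind, coords)
  wt <- weld_tolerance * spec$edge_length
  key <- paste(round(all_xyz[, 1] / wt), round(all_xyz[, 2] / wt),
               round(all_xyz[, 3] / wt))
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  vertices <- all_xyz[uk, , drop = FALSE]

  faces <- list(); labels <- character(0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  offset <- 0L
  for (i in seq_along(fcycles)) {
    n <- fcycles[[i]]
    ids <- vid[(offset + 1L):(offset + n)]
    offset <- offset + n
    # collapse consecutive duplicates (wedge vertices shared on fold edges)
    dup <- ids == c(ids[-1], ids[1])
    ids <- ids[!dup]
    if (length(ids) < 3L) next
    fkey <- paste(sort(ids), collapse = " ")
    if (!is.null(seen[[fkey]])) next
    seen[[fkey]] <- TRUE
    faces[[length(faces) + 1L]] <- ids
    labels <- c(labels, flabels[[i]])
  }

  mesh <- structure(list(vertices = vertices, faces = faces, labels = labels,
                         design = design),
                    class = "capsid_mesh")
  mesh <- orient_outward(center_mesh(mesh))
  validate_mesh(mesh)
  if (mirror) mesh <- mirror_mesh(mesh)
  if (project_to_sphere) mesh <- project_sphere(mesh)
  mesh
}

center_mesh <- function(mesh) {
  mesh$vertices <- sweep(mesh$vertices, 2, colMeans(mesh$vertices))
  mesh
}

orient_outward <- function(mesh) {
  for (i in seq_along(mesh$faces)) {
    ids <- mesh$faces[[i]]
    v <- mesh$vertices[ids, , drop = FALSE]
    # Newell normal
    nx <- sum((v[, 2] - v[c(2:nrow(v), 1), 2]) * (v[, 3] + v[c(2:nrow(v), 1), 3]))
    ny <- sum((v[, 3] - v[c(2:nrow(v), 1), 3]) * (v[, 1] + v[c(2:nrow(v), 1), 1]))
    nz <- sum((v[, 1] - v[c(2:nrow(v), 1), 1]) * (v[, 2] + v[c(2:nrow(v), 1), 2]))
    if (sum(c(nx, ny, nz) * colMeans(v)) < 0)
      mesh$faces[[i]] <- rev(ids)
  }
  mesh
}

mirror_mesh <- function(mesh) {
  mesh$vertices[, 1] <- -mesh$vertices[, 1]
  mesh$faces <- lapply(mesh$faces, rev)
  mesh
}

project_sphere <- function(mesh) {
  r <- sqrt(rowSums(mesh$vertices^2))
  mesh$vertices <- mesh$vertices * (mean(r) / r)
  mesh
}

# every undirected edge must be shared by exactly 2 faces, traversed in
# opposite directions (closed orientable 2-manifold)
validate_mesh <- function(mesh) {
  ecount <- new.env(hash = TRUE, parent = emptyenv())
  for (f in mesh$faces) {
    nn <- length(f)
    for (e in seq_len(nn)) {
      a <- f[e]; b <- f[e %% nn + 1L]
      ku <- paste(min(a, b), max(a, b))
      ecount[[ku]] <- c(if (!is.null(ecount[[ku]])) ecount[[ku]], sign(a - b))
    }
  }
  keys <- ls(ecount)
  cnt <- vapply(keys, function(kk) length(ecount[[kk]]), integer(1))
  if (any(cnt != 2L))
    stop("non-manifold mesh: ", sum(cnt != 2L),
         " edges not shared by exactly 2 faces")
  opp <- vapply(keys, function(kk) sum(ecount[[kk]]) == 0, logical(1))
  if (!all(opp))
    stop("non-orientable mesh: ", sum(!opp),
         " edges traversed twice in the same direction")
  V <- nrow(mesh$vertices); E <- length(keys); F <- length(mesh$faces)
  if (V - E + F != 2L)
    stop(sprintf("mesh Euler characteristic is %d, expected 2", V - E + F))
  invisible(TRUE)
}

#' Dual polyhedron of a mesh
#'
#' Places one dual vertex at the centroid of each face and connects vertices
#' of adjacent faces: the dual face around each primal vertex is the cycle of
#' its incident faces.  Dual V = primal F, dual F = primal V.  For a design
#' mesh the dual tiles are labeled by the design's Laves tile shape
#' (triangle, rhomb, floret or kite).
#'
#' @param mesh a `capsid_mesh`.
#' @return A `capsid_mesh` of the dual polyhedron.
#' @export
build_dual <- function(mesh) {
  stopifnot(inherits(mesh, "capsid_mesh"))
  validate_mesh(mesh)
  dmap <- new.env(hash = TRUE, parent = emptyenv())
  incident <- vector("list", nrow(mesh$vertices))
  for (i in seq_along(mesh$faces)) {
    f <- mesh$faces[[i]]
    nn <- length(f)
    for (e in seq_len(nn)) {
      a <- f[e]; b <- f[e %% nn + 1L]
      assign(paste(a, b), i, envir = dmap)
      incident[[a]] <- c(incident[[a]], i)
    }
  }
  centroids <- t(vapply(mesh$faces, function(f)
    colMeans(mesh$vertices[f, , drop = FALSE]), numeric(3)))
  tile <- if (!is.null(mesh$design) && !isTRUE(mesh$design$dual))
    unname(DUAL_TILE_SHAPE[mesh$design$lattice]) else "dual_tile"
  dual_faces <- vector("list", nrow(mesh$vertices))
  for (v in seq_len(nrow(mesh$vertices))) {
    f0 <- incident[[v]][1]
    walk <- integer(0); fi <- f0
    repeat {
      walk <- c(walk, fi)
      f <- mesh$faces[[fi]]
      pos <- match(v, f)
      pred <- f[(pos - 2L) %% length(f) + 1L]
      fi <- get(paste(v, pred), envir = dmap)
      if (fi == f0) break
    }
    dual_faces[[v]] <- walk
  }
  design <- mesh$design
  if (!is.null(design)) {
    design$dual <- !isTRUE(design$dual)
    if (design$dual)
      design$convention <- default_convention(design$lattice, TRUE)
    else design$convention <- default_convention(design$lattice, FALSE)
  }
  dual <- structure(list(vertices = centroids, faces = dual_faces,
                         labels = rep(tile, length(dual_faces)),
                         design = design),
                    class = "capsid_mesh")
  dual <- orient_outward(center_mesh(dual))
  validate_mesh(dual)
  dual
}

#' Face census measured on a mesh
#'
#' Counts faces by label and computes V, E, F from the mesh itself (the
#' independent check on the closed-form [face_census()]).
#'
#' @param mesh a `capsid_mesh`.
#' @return Object of class `face_census` (with `dual_tiles` = V for primal
#'   meshes, and the tile count in `dual_tiles` for dual meshes).
#' @export
mesh_census <- function(mesh) {
  stopifnot(inherits(mesh, "capsid_mesh"))
  validate_mesh(mesh)
  V <- nrow(mesh$vertices); F <- length(mesh$faces)
  E <- sum(lengths(mesh$faces)) / 2
  tab <- table(mesh$labels)
  g <- function(nm) if (nm %in% names(tab)) as.integer(tab[[nm]]) else 0L
  is_dual <- !is.null(mesh$design) && isTRUE(mesh$design$dual)
  tile_shape <- if (!is.null(mesh$design))
    unname(DUAL_TILE_SHAPE[mesh$design$lattice]) else NA_character_
  structure(list(vertex_polygons = g("vertex_polygon"),
                 hexagons = g("hexagon"), triangles = g("triangle"),
                 squares = g("square"),
                 dual_tiles = if (is_dual) F else V,
                 tile_shape = tile_shape,
                 V = V, E = as.integer(E), F = F),
            class = "face_census")
}

#' Geometric measures of a mesh
#'
#' Surface area (fan triangulation of each face about its centroid), volume
#' (signed tetrahedra about the centroid of the solid) and radial statistics,
#' in lattice-edge units.
#'
#' @param mesh a `capsid_mesh`.
#' @return List with `surface_area`, `volume`, `mean_radius`, `radius_range`.
#' @export
mesh_measures <- function(mesh) {
  stopifnot(inherits(mesh, "capsid_mesh"))
  v <- sweep(mesh$vertices, 2, colMeans(mesh$vertices))
  area <- 0; vol <- 0
  for (f in mesh$faces) {
    p <- v[f, , drop = FALSE]
    cen <- colMeans(p)
    nn <- nrow(p)
    for (e in seq_len(nn)) {
      a <- p[e, ]; b <- p[e %% nn + 1L, ]
      cr <- crossprod3(a - cen, b - cen)
      area <- area + sqrt(sum(cr^2)) / 2
      # signed tetrahedron (origin, cen, a, b)
      vol <- vol + sum(cen * crossprod3(a, b)) / 6
    }
  }
  r <- sqrt(rowSums(v^2))
  list(surface_area = area, volume = abs(vol), mean_radius = mean(r),
       radius_range = range(r))
}

#' @export
print.capsid_mesh <- function(x, ...) {
  cen <- mesh_census(x)
  lab <- if (!is.null(x$design))
    t_label(x$design$lattice, x$design$hk[1], x$design$hk[2], x$design$dual)
  else "mesh"
  cat(sprintf("Capsid mesh %s: V = %d, E = %d, F = %d\n",
              lab, cen$V, cen$E, cen$F))
  print(table(x$labels))
  invisible(x)
}
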