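---
title: "Capsid architectures from Archimedean lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capsid architectures from Archimedean lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archicapsid)
```

## The geometric model

Caspar–Klug (CK) theory models an icosahedral capsid as a hexagonal lattice
wrapped onto an icosahedron: 12 hexagons at the five-fold vertices become
pentagons, and the spacing of those pentagons along the hexagonal
coordinates $(h,k)$ fixes the triangulation number

$$T(h,k) = h^2 + hk + k^2,$$

giving capsids of $60T$ proteins in 12 pentamers and $10(T-1)$ hexamers.
The generalization implemented here replaces the hexagonal lattice with any
uniform (Archimedean) plane tiling that contains a hexagonal sublattice.
Exactly four of the eleven uniform tilings qualify: the hexagonal $(6,6,6)$,
trihexagonal $(3,6,3,6)$, snub hexagonal $(3^4,6)$ and rhombitrihexagonal
$(3,4,6,4)$ lattices.  The same pentagon-insertion construction then yields
four infinite families of icosahedral polyhedra (and four more from the dual,
Laves, tilings), with scaled size index

$$T_j(h,k) = \alpha_j \, (h^2 + hk + k^2),$$

where $\alpha_j$ is the area of the $(1,0)$ facet triangle relative to the
hexagonal case at equal edge length: $\alpha_t = 4/3$, $\alpha_s = 7/3$ and
$\alpha_r = 4/3 + 2/\sqrt{3} \approx 2.49$.  In the package these values are
not stored constants so much as invariants: the hexagon-center spacing of
each lattice model must satisfy $s^2/3 = \alpha_j$, and every planar patch
must integrate to $\alpha_j T A_0$, which the test suite checks to machine
precision.

The same construction applied to an octahedron (6 square insertions, each
retaining 4/6 of a hexagon) gives the octahedral counterparts; at
$(h,k)=(1,0)$ the eight families start at the eight hexagon-free Archimedean
solids (dodecahedron through rhombicuboctahedron), which serve as ground
truths for the mesh builder.

## Lattice models

Each lattice is realized at polygon edge length 1 with the hexagonal
sublattice spanned by $a_1 = (s, 0)$ and $a_2 = \mathrm{rot}_{60}(a_1)$.
The published construction specifies the tilings only by their vertex
symbols, so the face motifs are reconstructed from the standard uniform
tilings:

* **hexagonal** — hexagons on the $s = \sqrt{3}$ triangular lattice;
* **trihexagonal** — hexagons at spacing 2 meeting at vertices, with the
  medial triangles of the sublattice filling the gaps;
* **snub hexagonal** — the unit triangular tiling in which the six triangles
  around every vertex of an index-7 (knight's-move $(2,1)$) sublattice are
  merged into hexagons, leaving eight triangles per hexagon.  This is the
  only chiral lattice; the unmirrored construction is labeled `levo` and its
  reflection `dextro` (the assignment of names is a package convention);
* **rhombitrihexagonal** — hexagons at spacing $1+\sqrt{3}$ joined by unit
  squares across each sublattice edge and unit triangles at each sublattice
  triangle center.

Transcription errors in these motifs cannot pass silently: the $\alpha$
invariant, the patch-area conservation law and the mesh census would all
fail.

## Face censuses and stoichiometry

For icosahedral designs the closed forms are: 12 vertex pentagons,
$10(T-1)$ hexagons, $\{0, 20, 80, 20\}\,T$ triangles and
$\{0, 0, 0, 30\}\,T$ squares across the four lattices, with
$V = \{20, 30, 60, 60\}\,T$.  The triangle and square coefficients follow
from area bookkeeping — summed face areas must equal
$20\,\alpha_j T A_0$ with each symmetry vertex retaining $5/6$ of a hexagon
— combined with Euler's relation, and are locked independently by censuses
of the constructed meshes.  One wording subtlety: the $(1,0)$
rhombitrihexagonal facet carries its squares as three *half*-squares
centered on the facet edges, so the family has $30T$ squares even though a
single facet is often described as containing "one square"; the
rhombicosidodecahedron ($T=1$, 30 squares) settles the count.

Protein counts attach to faces through a *tile convention*.  The strict CK
rule (`ck_strict`) assigns proteins equal to the tile's rotational symmetry:
pentagons 5, hexagons 6, triangles 3, squares 4.  On the trihexagonal
lattice this splits naturally into $60T$ major capsid proteins (pentamers +
hexamers) and $60T$ minor capsid proteins (3 per interstitial triangle) —
the `trihex_edge_to_edge` convention.  `gyrated_trihex` models the
non-edge-to-edge variant in which triangles are rescaled to 3/5 of the
pentagon area so all footprints are equal; the MCP/mCP distinction then
disappears but the total $120T$ is unchanged.  Dual tilings carry per-tile
counts: 3 per triangle, $p \in \{2,4,6\}$ per rhomb (`rhomb_order_p`,
giving the $60T$/$120T$/$180T$ series), and 3 domains per kite
(`kite_protomer`, one three-domain protomer per tile).  Because the
published framework relaxes the symmetry rule for floret tiles without
fixing a count, `floret` takes proteins-per-tile as an explicit parameter
(default 6); results for it should be read as parameterized predictions.
Stoichiometries for the regular primal snub and rhombitrihexagonal lattices
are emitted with a `hypothetical` flag since no capsid examples are known.

## Mesh construction

`build_polyhedron()` folds the planar patch onto the solid without any
polygon clipping:

1. every lattice face whose centroid lies in the closed facet triangle
   (excluding the three corner hexagons) is instantiated once per facet;
2. a face vertex inside the triangle maps by the facet's isometry; a vertex
   beyond one facet edge maps by that isometry *folded* across the edge onto
   the neighboring facet plane.  This single-fold extension is exact because
   each of the four lattices has a 2-fold rotation center at the midpoint
   between adjacent hexagon centers and a 3-fold center at the facet
   centroid, so the lattice overlays of adjacent facets agree along shared
   edges.  A vertex beyond two edges would fall into the wedge removed at a
   symmetry vertex and raises a hard error (it does not occur for any
   admissible design);
3. faces with centroid exactly on a fold edge are generated from both
   adjacent facets and deduplicated after welding;
4. the twelve (or six) vertex polygons are assembled by walking the facets
   around each symmetry vertex and collecting the corner-hexagon vertices
   inside each facet's 60° wedge;
5. vertices are welded by quantized-coordinate hashing at
   $10^{-6}$ × lattice edge (errors from the isometries are at the
   $10^{-12}$ level, so the two scales are well separated), faces are
   oriented counter-clockwise from outside by their Newell normals, and the
   mesh is validated as a closed orientable 2-manifold with Euler
   characteristic 2.

Faces straddling fold edges are kept as single, bent cycles; this is why
measured surface areas differ from the planar bookkeeping by up to ~2%
(e.g. the trihexagonal/hexagonal area ratio at $(2,1)$ measures 1.355
against $\alpha_t = 4/3$), while the *combinatorial* census is exact.
Point classification against the facet uses signed edge distances with a
centralized tolerance of $10^{-9}$ × hexagon spacing.  Duals place one
vertex at each face centroid and one face per primal vertex (the cycle of
its incident faces); dual-of-dual is checked to be a combinatorial
involution.  Meshes are built at lattice edge 1 and carry no physical
units; nanometers enter only through the classifier's ratio tests.
Enantiomorphs (`mirror = TRUE`) are produced by reflecting the finished
mesh, which is equivalent to building from the reflected lattice.

The gyrated trihexagonal variant fixes only the 3:5 triangle:pentagon area
ratio, not a full set of tile shapes, so gyrated designs are available in
the catalog and stoichiometry but have no mesh constructor.

## The classifier

`classify_by_counts()` scans the enumerated catalog (default bound
$T_j \le 50$, all lattices, both symmetry classes, all conventions) and
requires *exact* integer agreement on every provided field — the theory is
exact, so no fuzzy matching is offered.  Pentamer counts match only
icosahedral designs; the `portal` option accepts 11 observed pentamers as
12 positions with one occupied by a portal complex.  An empty hit list is
informative: 1080 proteins under the strict hexagonal convention alone
would require the forbidden $T = 18$.  `radius_ratio_test()` compares an
observed radius ratio with $\sqrt{\alpha_a T_a / (\alpha_b T_b)}$ and
reports the relative deviation without a verdict, since the framework
states no acceptance threshold.

## Problem sizes and limitations

The test suite exercises patches to $h,k \le 4$, full mesh/census
equivalence for all four lattices and both symmetries to $h,k \le 3$
(largest mesh: snub $(3,3)$, $V = 1620$), classifier round-trips over the
catalog to $T_j \le 20$ and CK representability to $T \le 100$; these sizes
cover every worked example in the framework while keeping the default test
run to about a minute.

What passing tests do *not* show: the package reasons about idealized
lattice geometry only.  It does not fit atomic structures or density maps,
does not detect lattices from coordinates, does not model elongated
(prolate) capsids, multi-layer/radially coupled lattices, assembly
pathways or mechanical stress, and treats portal vertices merely as a
counting allowance.  Surface-area comparisons of real capsids require
deposited structures and are out of scope; the corresponding internal check
is the $\alpha$-ratio area invariant on generated meshes.
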