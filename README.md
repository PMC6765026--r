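# archicapsid

Icosahedral and octahedral virus capsid architectures from Archimedean
lattices.

## The problem

Caspar–Klug (CK) quasi-equivalence theory classifies icosahedral virus
capsids by the triangulation number `T(h,k) = h² + hk + k²`, predicting
shells of `60T` coat proteins in 12 pentamers and `10(T−1)` hexamers.  A
growing list of structures breaks this rule: phage Basilisk has 1080
proteins (`T = 18` is geometrically forbidden), herpesviruses carry a
secondary network of trimeric minor capsid proteins, picobirnavirus is a
"forbidden `T = 2`", and Tobacco ringspot virus builds a pseudo-`T = 3`
shell from three-domain protomers.

These outliers are explained by generalizing the CK construction from the
hexagonal lattice to all four Archimedean plane tilings that contain a
hexagonal sublattice — hexagonal `(6,6,6)`, trihexagonal `(3,6,3,6)`, snub
hexagonal `(3⁴,6)` and rhombitrihexagonal `(3,4,6,4)` — and to their dual
(Laves) tilings.  Replacing 12 hexagons by pentagons (or 6 by squares for
octahedral shells) yields eight families of polyhedral blueprints indexed by
the scaled triangulation number

    T_j(h,k) = α_j · (h² + hk + k²),   α_t = 4/3,  α_s = 7/3,  α_r = 4/3 + 2/√3

with predicted protein stoichiometries, capsomer layouts and size scalings
(`R_a/R_b = √(α_a T_a / α_b T_b)` at equal protein footprint).

`archicapsid` implements this framework for structural virologists and
protein-cage designers: it enumerates the design catalog in closed form,
folds explicit 3D polyhedral meshes for any design (with dual construction
and OFF/OBJ export), and solves the inverse problem of classifying observed
protein/capsomer counts and radius ratios against the catalog.

## Worked example

Phage Basilisk has 1080 coat proteins: 540 major (MCP) and 540 minor (mCP).
The trihexagonal design at `(h,k) = (3,0)` predicts exactly that:

```r
library(archicapsid)

stoichiometry(capsid_design("trihexagonal", 3, 0))
#> Stoichiometry for T_t(3,0)=12 (ck_strict): 1080 proteins (540 MCP + 540 mCP)
#>      unit multiplicity proteins_each
#>  pentamer           12             5
#>   hexamer           80             6
#>    trimer          180             3
```

The 12 pentamers and 80 hexamers carry the MCPs (`5·12 + 6·80 = 540`); the
180 interstitial triangles carry three mCPs each.  Running the inverse
problem recovers the design:

```r
classify_by_counts(capsid_observables(n_total = 1080, n_MCP = 540))
#>      T_label    symmetry  dual          convention n_MCP n_mCP n_total matched_fields
#>  T_t(3,0)=12 icosahedral FALSE           ck_strict   540   540    1080  n_total n_MCP
#>  T_t(3,0)=12 icosahedral FALSE trihex_edge_to_edge   540   540    1080  n_total n_MCP
```

(no classical CK design exists: `1080/60 = 18` is not of the form
`h² + hk + k²`).  The explicit polyhedron confirms the census:

```r
build_polyhedron(capsid_design("trihexagonal", 3, 0))
#> Capsid mesh T_t(3,0)=12: V = 270, E = 540, F = 272
#>        hexagon       triangle vertex_polygon
#>             80            180             12
```

Size predictions work the same way.  Tobacco ringspot virus (radius
15.4 nm, kite tiling `T_r^D(1,0)`) against Pariacoto virus (17.2 nm,
triangle tiling `T^D(1,1)`):

```r
radius_ratio_test(15.4, 17.2,
                  capsid_design("rhombi", 1, 0, dual = TRUE),
                  capsid_design("hex", 1, 1, dual = TRUE))
#> observed ratio 0.8953, predicted 0.9107, relative deviation 1.68%
```

The observed ratio ≈ 0.90 sits within 2% of the predicted ≈ 0.91, while the
same-lattice alternative `√(1/3) ≈ 0.58` misses by > 50%.

## Command line

A thin wrapper over the same functions lives in `exec/archicapsid`:

```sh
archicapsid catalog  --max-T 12 --out designs.csv
archicapsid build    --lattice trihexagonal --h 3 --k 0 --out basilisk.off
archicapsid classify --total 1080 --mcp 540
archicapsid ratio    --ra 15.4 --rb 17.2 --design-a rhombi:dual:1,0 --design-b hex:dual:1,1
```

Design strings use `<lattice>[:dual]:h,k[@convention]` with aliases `hex`,
`trihex`, `snub`, `rhombi`.  All output is deterministic.

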