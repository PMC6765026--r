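Package: archicapsid
Title: Icosahedral and Octahedral Virus Capsid Architectures from Archimedean Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates and constructs the families of polyhedral capsid
    blueprints that arise from the four Archimedean plane tilings containing a
    hexagonal sublattice (hexagonal, trihexagonal, snub hexagonal and
    rhombitrihexagonal) and from their dual (Laves) tilings. Generalizes the
    Caspar-Klug triangulation number to scaled T-numbers, predicts major and
    minor capsid protein stoichiometries and capsid size scalings, folds planar
    lattice patches into explicit 3D polyhedral meshes (with dual construction
    and OFF/OBJ export), and classifies observed capsid data (protein and
    capsomer counts, radius ratios) against the resulting catalog.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
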