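Package: disorderkit
Title: Modelling Disorder in Small-Molecule Crystal Structures from
    Molecule-in-Cluster Computations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for refining disordered small-molecule crystal structures.
    Splits a disordered model (SHELX ins/res or CIF) into ordered archetype
    structures, expands each archetype into a symmetry-generated cluster of
    whole neighbour molecules for fixed-environment geometry optimization
    against a pluggable tight-binding backend, derives archetype-specific
    bond (DFIX) and angle (DANG) distance restraints plus proximity-based
    EADP/EXYZ/SIMU constraints for least-squares refinement, and classifies
    the disorder as static or dynamic from archetype energy differences,
    interconversion barriers and Boltzmann populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    igraph,
    ggplot2,
    generics,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
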