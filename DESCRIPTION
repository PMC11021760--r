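Package: fraggrow
Title: Fragment-Based De Novo Ligand Growth in Protein Binding Pockets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated fragment-based structure generator for small-molecule
    ligand design. Starting from probe fragments placed at pharmacophore
    hotspots of a protein binding pocket, molecules are grown iteratively by
    graph-level linking rules (direct bond, linker-mediated bridge, ring
    fusion, spiro junction), passed through medicinal-chemistry filters,
    embedded in 3D, aligned to their parent pose, rigid-body docked against an
    empirical interaction field, and selected by docking energy or
    protein-ligand interaction score, optionally diversified by interaction-
    fingerprint clustering. Includes a regrow-and-reproduce benchmark that
    fragments a reference ligand, re-grows it in its own pocket and measures
    symmetry-aware RMSD to the crystal pose, plus a deterministic toy-complex
    fixture generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    bio3d,
    igraph,
    dplyr,
    tibble,
    rlang,
    generics,
    ggplot2,
    yaml,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
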