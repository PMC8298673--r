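Package: g2s
Title: Energy-Free 3D Structure Prediction from Molecular Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
                  email = "author@example.org")
Description: Graph-To-Structure (G2S) modelling: kernel ridge regression
    over graph-based molecular representations (bond order, bond hop,
    bond length, graph Coulomb matrix, graph Bag-of-Bonds, FLLA) predicts
    all pairwise interatomic distances of relaxed structures, and 3D
    coordinates are reconstructed by solving the distance-geometry
    problem with a classical-embedding plus stress-majorization solver,
    bypassing energy minimization.  Includes hydrogen placement on
    deterministic spherical grids, elpasolite crystal support with a
    lattice-constant machine, a synthetic constitutional-isomer fixture
    generator, learning-curve tooling and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    ChemmineR,
    ChemmineOB
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
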