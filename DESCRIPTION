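Package: ffcraft
Title: Force-Field Construction Toolkit for Small Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and refines molecular-mechanics force fields for small
    molecules. Provides molecular structure I/O (XYZ, PDB subset) with
    connectivity perception and dihedral manipulation; cosine-series torsion
    refitting against reference scans; Seminario extraction of harmonic bond
    and angle constants from a Cartesian Hessian; an interpolation-mechanics
    potential assembled from Shepard-weighted Taylor expansions in internal
    coordinates, with adaptive database construction driven by a pluggable
    analytic oracle potential; exhaustive and MD-based conformer generation
    with Boltzmann weighting; and a geometric solvation-box builder with
    counterion neutralization, Galvani-potential corrections, and GROMACS
    topology export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
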