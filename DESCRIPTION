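Package: dnamech
Title: Coarse-Grained Mechanics of DNA from Rigid-Base Coordinate Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers harmonic mechanical models of double-stranded DNA from
    ensembles of rigid-base coordinates (buckle, propeller, opening, shear,
    stretch, stagger; tilt, roll, twist, shift, slide, rise). Implements the
    non-local interacting-rigid-base model in which the stiffness matrix is
    the thermally scaled inverse of the full coordinate covariance, with
    deformation energies, conformational entropies, Schur-complement
    relaxation to coordinate subsets, single-coordinate force constants and
    non-dimensionalization. A complementary anisotropic elastic-rod
    description yields global roll, global tilt and total twist together
    with groove, backbone, isotropic bending and twist stiffness constants
    in length units. Includes nucleosome-threading deformation-energy
    profiles, a synthetic Gaussian trajectory generator with frame
    reconstruction for end-to-end validation, snapshot filtering on broken
    Watson-Crick hydrogen bonds, and plain-text/JSON file dialects with a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
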