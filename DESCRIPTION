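Package: excitonpmm
Title: Perturbed Matrix Method Excitonic Analysis of Pigment-Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing of molecular-dynamics ensembles of
    pigment-protein complexes with the perturbed matrix method (MD-PMM).
    For each environment configuration the electrostatic potential and
    field at a pigment's center of mass perturb its gas-phase electronic
    Hamiltonian; diagonalization yields per-frame site energies and
    perturbed transition dipoles. Point-dipole excitonic couplings and
    per-frame diagonalization of the Frenkel excitation matrix give
    exciton energies and per-pigment contribution weights, from which
    ensemble statistics, subpopulation analyses, and inhomogeneously
    broadened absorption line shapes are derived. A synthetic-data
    generator with a known ground truth and an independent brute-force
    reference implementation support end-to-end validation without
    external trajectory or quantum-chemistry data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
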