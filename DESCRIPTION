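Package: dpolkit
Title: Direct-Approximation Polarizable Electrostatics for Small Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and benchmarking polarizable electrostatic
    models under the direct polarization approximation, in which atom-centered
    isotropic point polarizabilities respond to permanent charges and external
    fields but never to other induced dipoles. Provides typed atomic
    polarizabilities fitted to field-perturbed electrostatic potential (ESP)
    differences, two-stage restrained ESP (RESP-dPol) charge fitting with the
    induced-dipole contribution included in the model ESP, bond charge
    correction (BCC-dPol) training and AM1-BCC-dPol charge assignment,
    Merz-Singh-Kollman style ESP grid generation, and post-processing
    estimators for liquid observables (mass density, static dielectric
    constant from dipole fluctuations, analytic high-frequency dielectric,
    Lorentz-Lorenz molecular polarizability). A synthetic ground-truth
    emulator generates baseline and field-perturbed ESP records from a known
    charge-plus-polarizability model so that every fitting procedure is
    testable by parameter recovery without a quantum-chemistry engine.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite, igraph, ChemmineR, pracma
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
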