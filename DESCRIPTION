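Package: cetanirs
Title: Feasibility Modeling of Near-Infrared Spectroscopy in Cetaceans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation pipeline for evaluating the feasibility of
    functional near-infrared spectroscopy (fNIRS) in medium-sized marine
    mammals such as dolphins. Builds wavelength-dependent tissue optical
    properties from a chromophore composition model and power-law
    scattering, estimates absorption and reduced scattering from
    multi-distance frequency-domain NIRS records, generates layered
    synthetic head phantoms with tetrahedral meshes, solves the
    continuous-wave diffusion equation with linear finite elements,
    computes adjoint sensitivity (Jacobian) matrices, and derives tissue
    sensitivity, depth sensitivity, regularized flatfield reconstruction,
    and large-detector power metrics across wavelength, source-detector
    separation, and body-size sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
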