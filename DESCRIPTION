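Package: secsans
Title: SEC-SANS Analysis of Protein Complexes in Solution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for size-exclusion chromatography coupled
    small-angle neutron scattering (SEC-SANS) of protein complexes:
    synthetic two-component elution runs with per-frame counting noise,
    scattergram peak detection and peak-averaged curve extraction,
    Guinier analysis with automatic window selection, regularized
    indirect Fourier transform to the pair-distance distribution P(r)
    with Dmax scanning, Kratky compactness diagnostics, analytic form
    factors (sphere, circular and elliptical cylinder) with bounded
    weighted least-squares fitting, ab initio dummy-atom shape
    reconstruction by simulated annealing under P1/P2 symmetry with
    model alignment, averaging and normalized spatial discrepancy
    scoring, and Debye-formula scattering from atomistic structures
    with neutron contrast handling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma,
    minpack.lm,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
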