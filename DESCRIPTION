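Package: holopr
Title: Propagation-Based X-Ray Phase Retrieval and Hologram Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for near-field (Fresnel-regime) X-ray phase-contrast
    imaging. Implements the full Fresnel propagator and its transport-of-
    intensity (TIE) and contrast-transfer-function (CTF) linearizations;
    direct filter-based phase retrieval (weak-object TIE, Paganin-type
    homogeneous TIE, multi-distance CTF, pure-phase CTF, and the mixed
    TIE/CTF approach with homogeneous, multi-material and heterogeneous
    priors); iterative refinement by steepest descent on the intensity
    misfit and by hybrid input-output / error-reduction projections with
    support and non-negativity constraints; cone-beam acquisition geometry
    with Fresnel scaling; a synthetic multi-distance hologram simulator
    with Poisson counting noise; and dataset handling (flat/dark
    correction, phase-correlation alignment, float TIFF I/O, parallel
    mapping over projections) with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    graphics,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
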