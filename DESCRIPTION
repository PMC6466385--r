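Package: myopk
Title: Three-Compartment Pharmacokinetics of a Photosensitizer in the
    Myocardial Interstitium from Plasma and Fluorescence Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the concentration of the photosensitizer talaporfin
    sodium in the myocardial interstitial space from serial plasma
    concentration measurements and relative myocardial fluorescence.  A
    linear three-compartment model (plasma, interstitial space, cell) is
    solved exactly in drug-amount space by eigendecomposition of the rate
    matrix; measured tissue fluorescence is modelled as a
    histology-weighted mixture of the three compartment concentrations,
    with mixture weights and compartment volumes derived deterministically
    from histomorphometry and subject physiology.  The five first-order
    rate constants are estimated by multi-start bound-constrained least
    squares on the pooled plasma and converted-fluorescence streams.
    Includes a synthetic-data generator replicating the canine study
    design and a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
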