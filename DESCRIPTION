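Package: beamtune
Title: Automated Beam-Model Parameter Tuning for Scanned Ion Beams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computer-driven commissioning of pencil-beam-scanning beam models
    for proton and light-ion therapy. Determines per-energy source parameters
    (mean energy, energy spread, and per-plane beam width, divergence, and
    emittance) from laterally integrated depth-dose curves in water and
    spot-size measurements in air, using sequential regularized least-squares
    tuning driven by a Nelder-Mead simplex, and compiles the tuned parameters
    into an energy-parametrized polynomial beam model. Ships an analytic
    forward engine (Fermi-Eyges lateral transport with Highland multiple
    Coulomb scattering in air, and a power-law Bragg curve with range
    straggling and energy-spread broadening) together with a synthetic
    commissioning-data generator, so the whole tuning pipeline can be
    exercised and validated by parameter recovery at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
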