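Package: ThermoTrace
Title: Active-Thermography Simulation and Hidden-Structure Detection
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-based transient heat-conduction simulation of active
    (pulsed) infrared thermography for two classes of hidden structure:
    plant root system architecture buried in soil behind an acrylic cover,
    and conical air bubbles inside plexiglass plates.  Provides parametric
    sample builders with ground-truth masks, an energy-conservative
    finite-volume solver (explicit and implicit time stepping with
    non-uniform depth layering), a line-scan local-minimum algorithm that
    recovers root structure from surface temperature sequences, polynomial
    regression, support vector machine and neural-network predictors of
    burial depth and bubble size with K-fold model selection, and a
    noise-injection battery for fault-tolerance profiling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    nnet,
    withr,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
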