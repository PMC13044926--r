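Package: mxsweep
Title: Rotation-Method Data-Collection Strategies for Macromolecular
    Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Plans and simulates rotation-method diffraction experiments on
    multi-axis goniostats. Provides point-group algebra for the eleven axial
    point groups, detector and mini-kappa goniostat geometry including a
    cone model of the phi-mount shadow, a radiation-damage dose budget and
    transmission calculator with a voxel dose simulator, a ray-tracing
    simulator of Ewald-sphere crossings with Lorentz factors, module-gap and
    blind-region bookkeeping, and generators for characterization, basic,
    advanced native and phasing strategies, including Dauter minimum sweep
    lengths, cusp filling and interleaving.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
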