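Package: scartherm
Title: Photothermal Simulation of Pulsed-Laser Treatment of Hypertrophic Scar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative photothermal modelling of pulsed dye laser therapy of
    hypertrophic scar and normal skin. Implements a Gaussian pulsed-beam
    volumetric heat source with Beer-Lambert axial attenuation, a transient
    axisymmetric finite-volume solver for the Pennes bioheat equation with a
    convective surface and fixed deep/lateral boundaries, Arrhenius
    thermal-damage accumulation with burn-degree classification, a factorial
    dose-parameter sweep (energy density, pulse width, spot diameter) with a
    temperature-threshold constrained dose selection rule, and a small
    histology utility for collagen-fiber area fractions from binary masks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
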