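Package: scleramech
Title: Scleral Biomechanics Simulation and Analysis for a Canine Glaucoma Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for whole-globe and scleral-strip
    biomechanics in an inherited canine open-angle glaucoma model. Provides a
    synthetic cohort generator with age- and genotype-structured tissue
    parameters, forward simulators and analyzers for bolus-infusion ocular
    rigidity (Friedenwald), dynamic mechanical analysis (complex modulus, loss
    tangent), exponential tensile-ramp fitting, A-mode ultrasound biometry, and
    high-frequency ultrasound inflation testing with radiofrequency speckle
    tracking and least-squares strain estimation, plus the cohort-level
    age/genotype regression stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
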