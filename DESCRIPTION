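Package: punctaflux
Title: Quantifying In Vivo Protein Complex Assembly from Fluorescence
    Heterogeneity and NAD(P)H Redox Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the assembly and disassembly of the
    CP12-GapDH2-PRK enzyme complex in living cyanobacteria from two-channel
    (chlorophyll + eYFP) time-lapse microscopy, and to relate it to the
    cellular redox state measured as NAD(P)H fluorescence relaxation.
    Implements per-cell normalized-standard-deviation (coefficient of
    variation) heterogeneity traces over labeled cell masks, monoexponential
    assembly/disassembly kinetics fits, the photo-reducible NAD(P)H level and
    the dark oxidation-rate fit with an adaptive slope-threshold window, the
    light-intensity dose-response and heterogeneity-versus-oxidation-rate
    regressions, and enzyme-activity and calibration-curve computations.
    A synthetic-data module generates image stacks, NAD(P)H traces and assay
    traces with known ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
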