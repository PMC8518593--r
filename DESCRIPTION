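Package: lithomass
Title: Coccolith Mass and 3D Thickness from Opto-Electrochemical Dissolution Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for measuring the calcium carbonate content of individual
    coccoliths by opto-electrochemical acid titration. Time-lapse dark-field
    movies of a dissolving coccolith are segmented, the effective-radius decay
    is decomposed into its two kinetic regimes, and the per-pixel time to
    complete dissolution is converted into a 3D calcite thickness map, volume
    and mass. Companion reaction-diffusion models of electro-generated acid
    transport from a fibre microelectrode justify the constant-rate assumption
    (surface- vs transport-limited kinetics, electrolyte rate modifiers), a
    synthetic-movie generator provides ground-truth benchmarks, and allometry
    helpers fit the mass-length scaling across liths and species.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    tiff,
    deSolve,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
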