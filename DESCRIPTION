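Package: cvrconcord
Title: Voxel-Wise Concordance of Breath-Hold and Resting-State
    Cerebrovascular Reactivity Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compare breath-hold cerebrovascular reactivity (CVR) maps with
    resting-state estimates based on the amplitude of low-frequency
    fluctuations (ALFF).  Provides a seeded synthetic BOLD phantom generator
    with ground-truth reactivity, lag and tissue fields; personalised
    respiratory-waveform estimation and lagged-regression beta mapping for
    breath-hold runs; band-limited ALFF computation for resting runs; and
    threshold optimisation of map/mask and map/map overlap via accuracy and
    Dice coefficients, including two-dimensional cross-metric accuracy
    surfaces with forced-classification corner diagnostics, split-run
    self-concordance, and unthresholded map comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
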