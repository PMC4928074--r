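Package: cardiomap
Title: Optical Mapping Analysis for Cardiac Tissue Slice Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for voltage- and calcium-sensitive fluorescence
    movies of cardiac tissue slices: signal conditioning (spatial binning,
    low-pass filtering, drift removal, normalization, polarity orientation),
    per-pixel activation and duration mapping (activation at 50% upstroke,
    APD80/CaTD80 at 80% repolarization), conduction-velocity estimation by
    local plane fitting of activation maps, pacing-protocol analyses
    (restitution curves, effective refractory period from S1-S1 capture loss,
    capture ratios, automaticity detection, nodal-vs-working region
    classification), and group-comparison statistics (Welch t, one-way ANOVA
    with Tukey HSD). Includes a kinematic simulator that renders synthetic
    movies with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tiff,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
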