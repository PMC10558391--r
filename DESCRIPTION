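Package: glycoscope
Title: Multimodal Quantification of Collagen Glycation from Multiphoton,
    Raman and AFM Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify ribose-induced collagen glycation in
    decellularized pericardium-like tissue from three complementary
    modalities: two-channel multiphoton images (two-photon excited
    fluorescence and second-harmonic generation intensity ratios over
    randomly sampled regions of interest), Raman spectra (extended
    multiplicative signal correction against an untreated reference,
    band normalization, and from-scratch PLS-LDA classification with
    stratified k-fold cross-validation), and atomic-force-microscopy
    topographies (plane/line/polynomial flattening, RMS roughness as the
    second central moment, and collagen D-period measurement from line
    profiles). A seed-deterministic synthetic-data generator emulates
    untreated and glycated tissue so the whole pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
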