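Package: pupilfocus
Title: Through-Focus Optical Quality and Clinical Synthesis for Pharmacologic Miosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fourier-optics modeling of small-aperture (pharmacologically miosed)
    and dual-focus multifocal eye models for presbyopia: Zernike wavefronts,
    point-spread and optical transfer functions, the Visual Strehl ratio of the
    OTF (VSOTF), through-focus depth-of-focus analysis at the VSOTF >= 0.12
    acceptability criterion, and Snellen-E optotype convolution panels. A
    clinical-synthesis component encodes an arm-level table of pilocarpine,
    carbachol and phentolamine presbyopia trials and reproduces pupil-constriction
    deltas, formulation-level ranges, the 0.90 mm clinical-meaningfulness
    threshold, age-luminance pupil regressions, and retinal-illuminance
    trade-offs, plus a synthetic trial-table generator for testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    pracma,
    yaml
Suggests: testthat (>= 3.0.0), png, jsonlite, ggplot2
Config/testthat/edition: 3
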