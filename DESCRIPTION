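Package: caTrace
Title: Calcium Imaging Trace Analysis for Perfused Tissue Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for confocal calcium-imaging recordings of
    perfused acute tissue slices. Converts per-ROI raw fluorescence to
    bleach-corrected dF/F0, classifies stimulus-evoked responses by a
    baseline mean + k*SD / minimum-duration criterion with vehicle-control
    and spontaneous-activity exclusions, estimates response onset delays,
    and aggregates calls into responder frequencies, response-profile
    overlaps, dose-response curves and repeated-stimulation normalizations
    with the matching nonparametric and contingency-table statistics. A
    seeded synthetic-recording generator with ground-truth labels makes the
    whole pipeline testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
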