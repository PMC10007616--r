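Package: ddmhsa
Title: Dual-Channel Heart Sound Analysis from Phonocardiogram and
    Photoplethysmogram
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection and S1/S2 labelling of heart sounds in
    phonocardiogram (PCG) recordings, fusing an acoustic branch
    (analytic-signal envelope, envelope filtering, Shannon-entropy peak
    enhancement, Savitzky-Golay smoothing, impulse thresholding) with
    photoplethysmogram (PPG) systolic-peak timing through the vascular
    transit time. Includes three model variants (plain, windowed,
    windowed plus envelope filtering), an event-detection evaluation
    suite with tolerance matching and sensitivity, precision,
    specificity and accuracy reports, the published per-subject
    benchmark counts of a 20-subject cohort, and a seeded generator of
    synchronised synthetic PCG/PPG recordings with ground-truth
    annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
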