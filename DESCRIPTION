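Package: phonoseg
Title: Envelope-Based Heart Sound Detection and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Real-time-capable detection and classification of the first (S1)
    and second (S2) heart sounds in phonocardiograms. Extracts the signal
    envelope by the Hilbert transform or by the per-frame maximum of the
    short-time Fourier transform power spectral density, estimates the heart
    rate and systolic length from the envelope autocorrelation or an
    empirical linear heart-rate relation, and classifies envelope peaks with
    separate rule sets for normal and increased heart rates. S1 labels are
    scored against reference electrocardiogram R-peaks inside a tolerance
    window. Includes a synthetic phonocardiogram/electrocardiogram generator
    with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
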