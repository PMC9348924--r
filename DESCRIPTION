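Package: pcgscreen
Title: Heart-Sound Screening by Wavelet Denoising and Threshold Rules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for screening phonocardiogram (PCG) recordings for signs
    of cardiac disorder. Reads heart-sound signals from WAV files or serial
    data-logger CSV exports, denoises them with a multilevel symlet-4
    discrete wavelet transform and soft thresholding, extracts three
    discriminative statistics (absolute mean amplitude, amplitude variance,
    and mean wavelet-coefficient energy), and classifies each recording as
    healthy, unhealthy, or indeterminate using published per-feature
    decision boundaries combined by majority vote. Includes a parametric
    heart-sound simulator (S1/S2 events, optional systolic murmur, sensor
    noise) so the whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
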