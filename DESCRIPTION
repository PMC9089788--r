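Package: atriakit
Title: Murine Atrial Electrophysiology Analysis from Optical Mapping and Surface ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of murine atrial electrophysiology experiments:
    voltage-sensitive-dye optical mapping movies (beat segmentation, ensemble
    averaging, spatial smoothing, normalization, activation / upstroke-velocity /
    APD75 maps with region-of-interest summaries), single-lead surface ECG
    processing (R-peak detection, signal-averaged P/PR/QRS interval measurement,
    premature atrial complex labeling), atrial fibrillation episode detection with
    a per-day diagnosis rule, R-R variability metrics, delta-delta-Ct qPCR fold
    changes, and group-comparison statistics.  Ships a synthetic-data generator
    that emulates control and atrial AMPK-knockout phenotypes with known ground
    truth, so the full pipeline is testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    signal,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
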