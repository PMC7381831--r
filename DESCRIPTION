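Package: slscpa
Title: Short-Lag Spatial Coherence Beamforming for Photoacoustic Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for coherence-based beamforming of photoacoustic
    radio-frequency channel data acquired with linear ultrasound arrays.
    Implements the full short-lag spatial coherence (SLSC) pipeline
    (channel regrouping, DC removal, analytic-signal transform, synthetic
    receive-aperture delays, ensemble coherence factors, lag compounding,
    normalization and log compression) alongside a conventional
    delay-and-sum (DAS) baseline; image-quality metrics (generalized
    contrast-to-noise ratio, lateral full width at half maximum, image and
    channel signal-to-noise ratios); a point-source channel-data simulator
    with calibrated Gaussian channel noise; a simulated visual-servoing
    loop with morphological target segmentation; and a laser-safety
    calculator for skin maximum permissible exposure and per-pulse fiber
    energy limits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    EBImage,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    optparse
Config/testthat/edition: 3
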