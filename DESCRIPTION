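Package: sarcospace
Title: Sarcomere and T-Tubule Spacing from Fluorescence Line Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Measures striation spacing (sarcomere length or T-tubular
    distance) in fluorescence images of cardiac myocytes. Intensity
    profiles are extracted along a line region of interest, averaged
    across its width, and fitted with a sum of Gaussians plus a linear
    offset by the Levenberg-Marquardt algorithm; spacing is the distance
    between centers of adjacent fitted peaks, with low-intensity peaks
    excluded. Includes frame superposition for signal-to-noise
    improvement, a tilt-projection overestimation factor, Welch's t-test
    (raw data or summary statistics), the Steel-Dwass all-pairs
    nonparametric test, and a synthetic striated-image generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    pracma,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
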