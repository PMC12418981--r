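Package: pflowr
Title: Gradient-Vector Tracking (p-Flow) and Point-Light Displays for
    Nonrigid Motion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts a trackable subset of optical flow (the pseudo-flow,
    or p-flow) by matching spatiotemporal image-gradient vectors at the
    positions their own implied motion predicts in subsequent frames, and
    renders the result as point-light-display movies. Includes a
    from-scratch Lucas-Kanade feature tracker as the comparison algorithm,
    synthetic ground-truth scene generators (rigid translation and
    rotation, drifting gratings, and a divergence-free advected-noise
    fluid proxy with a viscosity-like smoothness parameter), flow-accuracy
    scoring against ground truth, and an analysis pipeline for viscosity
    rating experiments: anchored log-viscosity rating scales with
    expansion, moving-window error diagnostics, split-plot (one-between,
    one-within) ANOVA with Tukey post hoc tests and Bonferroni-corrected
    alpha, and a synthetic observer model for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse
Config/testthat/edition: 3
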