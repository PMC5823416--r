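Package: pyloruskit
Title: Locating the Pylorus in Capsule-Endoscopy Frame Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for automatically locating the stomach/small-intestine
    boundary (the pylorus) in wireless capsule-endoscopy frame sequences.
    Implements color-saliency detection in Lab space to mask out
    disturbances (bubbles, shadows, overexposure, fluid) and keep the valid
    tissue region of each frame; a Monitor-Judge temporal model that tracks
    window-pair color dissimilarity and triggers a classifier only on
    suspicious window pairs; a fused color-texture frame descriptor built
    from gray-level co-occurrence statistics of the phase-congruency
    maximum-moment map together with masked hue-saturation histograms; a
    radial-basis support-vector classifier that converts per-frame organ
    labels into a boundary estimate; confusion-matrix and frame-error
    evaluation utilities; and a seeded synthetic frame generator so the
    whole pipeline is testable without clinical video.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    grDevices,
    jsonlite,
    png,
    stats
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
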