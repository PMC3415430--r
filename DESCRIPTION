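Package: sensetrackr
Title: Single-Animal Posture Tracking and Sensorimotor Trajectory
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tracks the body posture of a single animal (a crawling
    Drosophila larva, or any dark-on-light or light-on-dark blob) in
    grayscale frame sequences of a two-dimensional arena, and
    reconstructs the sensory stimulus experienced at specific body loci
    in parametric stimulus landscapes (odor, temperature, light).
    Provides background reconstruction and segmentation, thinning-based
    skeletonization with head/tail identification and identity
    propagation, pixel-to-millimeter calibration, analytic stimulus
    fields with gradients, behavioral event detection (runs, turns,
    head casts), an experiment-scaling planner, and a synthetic
    crawling-animal generator with exact ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
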