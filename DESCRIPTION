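Package: phytowave
Title: Tracking and Transport Modeling of Traveling Calcium and Glutamate
    Waves in Plant Tissue
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of wound-triggered calcium and glutamate
    waves in fluorescence time-lapse imaging of plant tissue. Provides
    geometric intensity scanning of image stacks (radial fans from a wound
    site, arc-anchored radii from a droplet edge, perpendicular transects
    from a vein segment), LOESS-based traveling peak and front tracking with
    a baseline noise model, kinematic summaries across replicates
    (through-origin polynomial and linear fits, per-time-point group tests),
    and physical transport-model inference: power-law and diffusion front
    fits, Gaussian-process regression of tracer bulk flow, Taylor
    (shear-enhanced) dispersion wave prediction with channel-activation
    threshold fitting, and an exact paired sign test. A synthetic-data module
    generates image stacks and distance-time tables with known ground truth
    for parameter-recovery testing, and a small command-line layer ties the
    pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
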