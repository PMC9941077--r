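Package: suturemetrics
Title: Multiple-Metrics Assessment of Corneal Suturing Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative assessment of microsurgical corneal suturing
    sessions recorded under an operating microscope. Implements
    zone-occupancy analysis of instrument traces over a two-circle
    partition of the field of view, stitch-geometry metrics (length,
    length ratio, inter-stitch distance and angle), total and per-stitch
    times with a fixed penalty per uncompleted stitch, aggregation of a
    12-item suturing-quality rubric and of the RULA ergonomic score, and
    nonparametric group comparison (Kruskal-Wallis, Mann-Whitney) with a
    session-selection policy. A synthetic session generator with
    skill-group-dependent structure supports testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
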