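Package: larvagram
Title: Segment-Resolved Kinematics of Crawling Drosophila Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of fluorescence video of crawling
    Drosophila larvae with labelled musculature. Provides a ground-truthed
    synthetic video generator for the two larval motor programs
    (tail-to-head peristalsis and asymmetric anterior contraction),
    machine-vision extraction of the body outline, head/tail, centerline
    and signed bend angle, per-segment contraction and asymmetry
    kymographs, peristalsis-wave and head-sweep event detection, and
    run-and-turn navigation statistics for thermotaxis assays.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
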