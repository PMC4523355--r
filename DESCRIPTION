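Package: trackmorph
Title: Abundance, Morphology and Movement Behaviour from Microscopy Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained video-analysis work flow for quantifying
    populations and communities of moving organisms (e.g. aquatic protists)
    filmed under dark-field microscopy. Moving individuals are isolated by
    dynamic difference-image segmentation, measured with an ImageJ-style
    morphology descriptor set (fitted ellipse, circularity, solidity, ...),
    and linked into movement trajectories by cost-minimising assignment with
    gap closing. Per-trajectory summaries of morphology and movement are
    filtered by displacement, duration and detection-rate criteria, merged
    with experimental metadata, and converted to by-frame abundance
    estimates. A synthetic-video generator with full ground truth supports
    validation, and a proof-of-concept random-forest module demonstrates
    trait-based species identification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    tiff,
    randomForest,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
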