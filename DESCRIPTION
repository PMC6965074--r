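Package: wetmapr
Title: Wet-Area Mapping from High-Resolution Digital Elevation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives hydrologically informed terrain indices from a
    high-resolution digital elevation model (cartographic depth-to-water,
    elevation above stream, topographic wetness index, multi-scale elevation
    roughness, and multi-threshold stream networks) and fuses them with
    ancillary layers through supervised classifiers trained on point
    soil-moisture observations, producing binary and probabilistic wet/dry
    soil maps with chance-corrected accuracy assessment. Includes a seeded
    synthetic-terrain generator emulating a boreal landscape so the whole
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    randomForest,
    e1071,
    nnet,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
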