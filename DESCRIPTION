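Package: ghostdet
Title: Lightweight Ghost-Convolution Networks for Detecting Aggression in
    Group-Housed Sheep
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Building blocks and a complete single-stage detector for
    recognising aggressive (head-impact) interactions in group-housed sheep
    from barn surveillance imagery. Implements ghost-module convolutions and
    their two information-exchange variants (pointwise and channel-shuffle),
    compress-first and inverted-residual ghost bottlenecks, an exact
    multiply-accumulate and parameter cost model with closed-form speedup and
    compression ratios, annotation-preserving weather augmentation (fog, rain,
    snow, mirroring, rotation-scaling), a seeded synthetic barn-scene
    generator with YOLO-format labels, anchor-grid decoding with non-maximum
    suppression, a from-scratch SGD training loop, and precision/recall/F1 and
    mean-average-precision evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
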