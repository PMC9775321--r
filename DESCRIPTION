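Package: wsattn
Title: Weakly Supervised Attention-Guided Classification of Brain MRI Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A weakly supervised, attention-guided pipeline for binary
    classification of 2D brain-MRI slices. Provides entropy-based slice
    selection from 3D volumes, a residual convolutional backbone whose
    bottleneck blocks carry a channel-plus-spatial attention gate, bilinear
    attention pooling into a part-feature matrix, attention-guided crop and
    drop data augmentation, a center-style attention regularization loss
    with moving-average part centers, and coarse-plus-fine fused test-time
    inference with confusion-matrix metrics. The network forward and
    backward passes are implemented natively so the whole pipeline trains
    and evaluates on CPU; a deterministic synthetic-slice generator with a
    planted lesion makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    png,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
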