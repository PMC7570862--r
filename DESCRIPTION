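Package: sdaehar
Title: Stacked Denoising Autoencoders for Wearable-Sensor Human Activity
    Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for recognising static, dynamic and
    transitional human daily activities from six-axis wrist-worn inertial
    sensor streams (tri-axial accelerometer and gyroscope). Provides a
    synthetic labelled-signal generator emulating a twelve-activity lab
    protocol, sliding-window segmentation into flattened fixed-length
    instances, class rebalancing by random over/under-sampling and SMOTE,
    a from-scratch stacked denoising autoencoder with greedy layer-wise
    pretraining and softmax fine-tuning, and confusion-matrix based
    precision/recall/F1 evaluation. All stages are deterministic under a
    seed and scriptable from a single run configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
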