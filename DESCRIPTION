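Package: drhybrid
Title: Hybrid Ensemble Fusion for Diabetic Retinopathy Severity Grading
Version: 0.1.0
Authors@R:
    person("drhybrid", "developers", email = "drhybrid@example.org",
           role = c("aut", "cre"))
Description: Tools for five-grade diabetic retinopathy severity grading from
    colour fundus photographs: black-border cropping and per-backbone
    resizing, training-time geometric augmentation, an ordinal
    "enhance cross-entropy" loss that penalises predictions by their grade
    distance from the truth, a registry of backbone classifiers with
    replaced softmax heads, three ensemble fusers of base-model probability
    outputs (averaging, fully-connected and convolutional stacking), the
    standard confusion-matrix evaluation metrics, and a synthetic-data
    module that makes the whole pipeline testable at desk scale on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    jpeg,
    jsonlite,
    optparse,
    digest,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
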