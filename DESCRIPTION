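Package: milfc
Title: Weakly-Supervised Prediction of Chromosome-Arm Fold Change from
    Whole-Slide Image Patch Bags
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multiple-instance learning for copy-number fold-change (FC)
    regression on whole-slide images of IDH-mutant gliomas. Tiles slides
    into 224x224 patches, filters background and blood, extracts per-patch
    features behind a frozen extractor interface, scores patches with a
    linear layer, aggregates the N highest and N lowest scores through a
    small multilayer perceptron into slide-level 1p and 19q FC estimates,
    and fuses the two arms into an astrocytoma/oligodendroglioma call by
    logistic regression. Includes the NGS mean-arm-FC and FISH
    signal-ratio labeling rules, red/blue/purple interpretability
    heatmaps, a bootstrap ROC evaluation harness with repeated 60/20/20
    splits, and a synthetic-slide generator so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
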