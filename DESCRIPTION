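Package: histolrp
Title: Explanation-Driven Quality Assurance for Histopathology Patch Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-wise explanation heatmaps for small convolutional tumour-patch
    classifiers via layer-wise relevance propagation (epsilon-rule for dense
    layers, alpha-beta-rule for convolutions), together with the controlled
    experiments needed to audit such classifiers for hidden dataset biases: a
    seeded generator of haematoxylin-eosin-like tissue tiles with per-cell
    point annotations and necrosis-like regions, ratio-controlled mini-batch
    training of a layered network, tile-level heatmap assembly and
    normalisation, cell-level ROC/AUC evaluation of heatmaps against point
    annotations, and five end-to-end experiments covering feature
    verification, class-sampling ratios, centre-labelling dataset bias,
    class-correlated corruption bias and tissue-type sampling bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
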