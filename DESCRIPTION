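Package: deepident
Title: Taxonomic Image Identification from Pretrained Convolutional Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A feature-transfer pipeline for fine-grained taxonomic
    identification of specimen images. Images are standardised to square
    inputs (aspect-preserving resize with random-pixel padding, or plain
    distortion), passed through a five-block convolutional backbone with the
    VGG16 layout, and per-block activation volumes are turned into classifier
    features by global or intermediate N x N spatial pooling, multilayer
    fusion, and signed-square-root normalisation. A linear one-vs-rest
    max-margin classifier is trained on the features and evaluated with
    stratified or specimen-grouped k-fold cross-validation, with per-category,
    top-k and sample-size diagnostics and t-SNE feature-space maps. A seeded
    synthetic specimen-image generator makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
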