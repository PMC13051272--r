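Package: canopyseg
Title: Robust UAV Forest-Canopy Segmentation with Environment-Simulation
    Augmentation and an Attention Context-Guided U-Net
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for pixel-level segmentation of tree canopies in
    high-resolution RGB imagery from unmanned aerial vehicles. Provides an
    environment-simulation augmentation framework (fog, local overexposure,
    directional motion blur, occlusion) alongside classic geometric and
    pixel-level augmentations with strict mask synchronization; three
    encoder operators (split-based convolution, criss-cross attention and
    context-guided downsampling) backed by an exact reverse-mode gradient
    engine; their assembly into a VGG16-backbone U-Net and its attention
    context-guided variant; confusion-matrix evaluation (IoU, pixel
    accuracy, precision, recall) and a deterministic cross-entropy training
    loop with a cosine learning-rate schedule. A built-in synthetic
    canopy-scene generator makes the whole pipeline testable without field
    imagery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    jsonlite,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
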