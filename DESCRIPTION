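Package: cervitex
Title: Texture-Based Cervigram Enhancement, Classification and Lesion Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting abnormal regions in photographic images of
    the uterine cervix (cervigrams). Images are contrast-enhanced by a
    directional variant of windowed histogram equalization in which the
    processed pixel occupies each of eight anchor positions of the sliding
    window, transformed with the exactly invertible finite ridgelet transform
    (1-D wavelets on finite Radon projections over a prime grid), and described
    by gray-level run-length statistics, rotation-invariant enhanced local
    ternary patterns, and Hu moment invariants. A feed-forward neural network
    classifies images as normal or abnormal under stratified k-fold
    cross-validation with a full confusion-matrix metric suite, and abnormal
    images are segmented by binary morphology (Otsu threshold, opening/closing,
    connected-component filtering) with Dice scoring against ground truth. A
    deterministic synthetic cervigram generator with per-image lesion masks
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
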