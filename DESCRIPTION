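Package: fibrotype
Title: Fiber Morphometry, Texture, and Machine-Learning Classification of
    Label-Free Multiphoton Skin Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies normal, keloid-scar, and scar-adjacent skin tissue
    from paired collagen (second harmonic generation) and elastin (two-photon
    excited fluorescence) channel images. Extracts 28 morphological and
    textural features per sample (density, FFT-based alignment fitted with a
    semicircular von Mises distribution, traced fiber width and length,
    histogram statistics, and gray-level co-occurrence matrix statistics),
    ranks them by minimum-redundancy maximum-relevance mutual information,
    builds incremental feature subsets, and evaluates a stochastic
    gradient-descent linear classifier with leave-one-out cross-validation
    and one-vs-rest ROC/AUC. Includes a seeded synthetic fiber-image
    simulator so the whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
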