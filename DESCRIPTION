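Package: lesiondx
Title: Dermoscopy Lesion Segmentation and Diagnosis with a Kernel Fuzzy
    C-Means Pipeline and an Improved Neural Network Optimizer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for computer-aided
    diagnosis of skin lesions from dermoscopy-style images: median-filter
    noise reduction and lookup-table contrast stretching; region-of-interest
    segmentation by SLIC superpixels, kernel fuzzy C-means and spectral
    clustering on a t-nearest-neighbour fuzzy-XOR affinity graph; extraction
    of 19 geometric, intensity, moment-invariant and grey-level co-occurrence
    descriptors; wrapper feature selection and support-vector-machine
    hyperparameter tuning driven by the neural network algorithm (NNA) and
    its improved variant (INNA) with logistic chaos-map initialization and
    Levy-flight weight updates; and a benchmark harness validating the
    optimizer on six standard test functions. Includes seeded generators for
    synthetic dermoscopy-like images with ground-truth masks and for labelled
    feature tables, so every stage is testable without external image
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
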