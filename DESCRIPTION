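Package: cdllc
Title: Convolutional Dictionary Learning with Local Constraint for Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-layer (deep) dictionary learning with a supervised atom-graph
    locality constraint and a jointly trained softmax classifier, for multi-class
    classification of grayscale images (e.g. brain tumor MR slices) or precomputed
    feature matrices. Provides orthogonal matching pursuit and K-SVD machinery for
    layer-wise initialization, a graph-Laplacian locality regularizer over
    last-layer dictionary atoms, an alternating full-batch optimizer with
    backpropagated gradients and closed-form factor updates, per-sample sparse
    encoding and softmax classification at test time, gray-level co-occurrence
    (Haralick) texture features, seeded synthetic-data generators, a stratified
    cross-validation and lambda grid-search evaluation harness, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
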