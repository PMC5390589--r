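Package: PCAHashNet
Title: PCA-Filter Convolutional Hashing Features for Imbalanced
    Medical Image Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A two-stage PCA-filter convolutional feature extractor for
    single-channel medical images, in the PCANet family. Eigenfilters are
    learned from mean-removed overlapping image patches, applied as
    zero-padded tanh convolutions with an elementwise nonlinear
    transformation, and pooled into fixed-length descriptors by Heaviside
    binary hashing, multiscale spatial-pyramid word histograms, high
    dispersal (fixed-norm rescaling) and local response normalization
    across filter maps. Includes a class-weighted linear support vector
    machine evaluation protocol (repeated stratified cross-validation,
    class-weight sweep, hyperparameter grid search, sensitivity /
    specificity / g-metric reporting) for unbalanced two-class problems,
    and a seeded generator of synthetic two-class tongue-like images for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, png, jpeg, tiff, e1071
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
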