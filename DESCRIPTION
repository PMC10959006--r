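Package: nirssl
Title: Class-Rebalanced Self-Training for Near-Infrared Leaf Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-supervised classification of leaf nutrient (nitrogen and
    potassium) status from near-infrared reflectance spectra. Implements
    iterative self-training with per-iteration class rebalancing of
    pseudo-labeled data (random, mean, reverse and SMOTE resampling),
    dot-product similarity screening of unlabeled hyperspectral pixels,
    Savitzky-Golay spectral smoothing, pluggable base classifiers (PLS-DA,
    LDA, random forest), macro/weighted precision-recall metrics, Gini
    wavelength-importance analysis, and a seeded synthetic-data generator
    emulating imbalanced five-class leaf spectra and hyperspectral leaf
    cubes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    randomForest,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
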