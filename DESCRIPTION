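Package: thermomics
Title: Deep-Learning Thermomics for Infrared Breast Thermography Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for breast-thermography screening from dynamic
    infrared image sequences. Thermal sequences are compressed by principal
    component thermography (PCT) or its sparse elastic-net variant into
    three-channel "avatar" images, from which a ResNet-50-architecture
    convolutional backbone extracts 2048 deep thermomic features; a sparse
    deep autoencoder reduces these to 16 latent thermomics, and a random
    forest with leave-one-out cross-validation stratifies symptomatic from
    healthy subjects. A finite-difference Pennes bioheat phantom simulator
    generates labeled synthetic cohorts so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    png,
    EBImage,
    ranger,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Software, Classification, DimensionReduction, FeatureExtraction
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'classify.R'
    'deep-features.R'
    'lowrank.R'
    'phantom-sim.R'
    'pipeline.R'
    'thermal-io.R'
    'thermoencoder.R'
    'thermomics-package.R'
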