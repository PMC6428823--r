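Package: nodulescan
Title: Lung Nodule Detection from CT Slices with Frequency-Domain
    Enhancement, Evolutionary Thresholding and Weber Texture Features
Version: 0.1.0
Authors@R: person("NoduleScan", "Developers", role = c("aut", "cre"),
    email = "maintainer@nodulescan.dev")
Description: A computer-aided detection (CAD) pipeline for pulmonary
    nodules in thoracic CT slices. Stages: contrast enhancement by
    contrast-limited adaptive histogram equalization applied to the
    low-frequency part of a block discrete cosine transform; lung-field
    segmentation by background removal, iterative Hounsfield-unit
    thresholding and differential-evolution optimal thresholding with
    corner-seeded region growing and hole filling; candidate extraction
    inside the lung mask with diameter and elongation pruning; Weber
    Local Descriptor texture features (differential excitation and
    gradient orientation block histograms); and a support vector
    machine for nodule versus non-nodule classification with the full
    evaluation protocol (stratified splits, k-fold cross-validation,
    sensitivity/specificity/accuracy, ROC). A synthetic thorax phantom
    generator with ground truth lets every stage and the end-to-end
    experiment run without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
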