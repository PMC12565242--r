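Package: ILDSlider
Title: Anatomy-Anchored Slice Selection and Slice-Level 3D Adapters for
    Progressive Fibrosing ILD Identification from Chest CT
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements an anatomy-anchored pipeline for identifying
    progressive fibrosing interstitial lung disease (PF-ILD) from a small
    number of chest CT slices. Three anatomical position markers (apical
    lung onset, tracheal bifurcation, upper diaphragm) are located by a
    slice classifier with peak slice mining, representative slices are
    selected at fixed fractional positions between the markers (3-, 5- or
    9-slice strategies), and a parameter-efficient slice-level 3D adapter
    ("Slider") inserted into a frozen vision-transformer backbone performs
    the case-level classification. Includes Hounsfield-unit multi-window
    RGB fusion and scanner-mask preprocessing, a synthetic CT phantom
    generator with known ground truth for end-to-end testing, exact
    tunable-parameter accounting for adapter and fine-tuning regimes, and
    classifier-comparison statistics (DeLong test, stratified paired
    bootstrap, score-swapping permutation test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Software
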