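Package: spontdyn
Title: Spatiotemporal Analysis of Spontaneous Wide-Field Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for millimeter-scale spontaneous activity in
    developing cortex imaged with fast wide-field calcium indicators.
    Converts raw fluorescence to baseline-corrected dF/F and prior-frame
    subtraction deconvolved activity, segments spontaneous events with
    morphological cleanup, estimates modular wavelength from radial spatial
    autocorrelation, builds seed-point correlation networks with
    rotation-surrogate null models, classifies static versus propagating
    events by propagation area, fits and permutation-tests linear traveling
    wavefronts with axial direction statistics, discovers repeated
    spatiotemporal motifs by permutation-calibrated greedy clustering, and
    quantifies how long template spatial patterns remain decodable with
    per-timepoint PCA and SVM classification. Includes a ground-truth
    synthetic movie generator so every stage is testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    cluster,
    e1071,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    withr,
    tidyr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
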