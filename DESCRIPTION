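Package: clotvh
Title: Virtual Histology of Blood Clots from Propagation-Based X-Ray Microtomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for non-contrast
    3D virtual histology of retrieved blood clots imaged by propagation-based
    X-ray microtomography. Provides a ground-truthed clot phantom generator and
    parallel-beam projection simulator with propagation edge enhancement and
    Poisson noise; Paganin-style single-material phase retrieval parametrised by
    the -6 dB cutoff of its low-pass filter and filtered back-projection
    reconstruction; two-point Hounsfield-like intensity calibration against air
    and a polystyrene (Kapton) tube; ordered multi-class composition
    segmentation with volume-fraction and mean-intensity quantification plus
    porosity sizing; multiscale 3D Frangi-filter detection of hyperintense red
    blood cell blobs; and Williamson-Hall crystallite-size and microstrain
    estimation from X-ray diffraction peak lists with instrumental-broadening
    correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    ggplot2,
    generics,
    rlang,
    jsonlite,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
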