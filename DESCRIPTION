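Package: headgeo
Title: Photogrammetry-Based EEG Electrode Localization and MRI Coregistration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for localizing EEG electrodes (and MEG markers) on
    textured photogrammetric head meshes and coregistering them to
    structural MRI space. Implements centroid-ratio scaling plus iterative
    closest point (ICP) facial-surface matching, texture binarization with
    multi-view circular Hough detection and back-projection, seven-template
    majority-vote electrode labeling, scalp-surface extraction from MRI
    volumes, chroma-key photo masking, and the evaluation machinery
    (nearest-vertex and per-electrode deviation reports, coregistration
    error simulation, exact Wilcoxon signed-rank tests). Includes a
    synthetic textured-head generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
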