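Package: mwbim
Title: Microwave Breast Imaging with Sectorized TR-MUSIC and Radiomic Lesion Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale computational chain for multistatic microwave breast
    imaging (MWBI). Simulates multistatic S21 radar scans of synthetic
    pendulous-breast phantoms immersed in a lossy transition liquid,
    preprocesses the scan data (PCA coupling removal, empirical mode
    decomposition, distance-based filtering, propagation loss compensation,
    amplitude filtering, with three operating modes), reconstructs 3D
    intensity volumes by sectorized wideband time-reversal MUSIC under
    parametric fibroglandular-content assumptions, extracts and validates
    regions of interest, computes a 25-feature radiomic vector (shape,
    first-order, GLCM, NGTDM), and quantifies malignant-versus-benign feature
    separability by one-way ANOVA together with a false-positive workflow for
    unspecified findings in healthy breasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
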