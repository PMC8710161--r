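Package: clonereg
Title: Clonal-Selection Optimization of Normalized Mutual Information
    Image Registration with Spectral-CT Effusion Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rigid/similarity registration of multimodal (PET-like vs
    CT-like) images by maximizing normalized mutual information with a
    clonal selection algorithm (an artificial-immune-system optimizer),
    together with a real-coded genetic-algorithm baseline, a paired
    synthetic-phantom benchmark that counts gross registration
    mismatches, and diagnostic statistics for benign versus malignant
    serous cavity effusion: Welch two-sample tests computed from group
    summary statistics of energy-resolved CT values and base-material
    concentrations, a seeded synthetic patient cohort generator, and
    ROC/Youden analysis (AUC, cutoff, sensitivity, specificity).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    RNifti,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
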