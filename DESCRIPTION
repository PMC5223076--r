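Package: trimodr
Title: Nonlinear Trimodal Regression of CT Radiodensitometric Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies skeletal muscle degeneration from CT by fitting a
    trimodal quasi-probability-density model (two skewed and one standard
    Gaussian component for fat, loose connective tissue, and normal muscle)
    to 128-bin Hounsfield-unit histograms over the soft-tissue window
    [-200, 200] HU. Provides CT-number to HU binning, tissue-interval
    classification, constrained nonlinear least-squares fitting with
    goodness-of-fit reporting, mean-HU and Welch t-test cohort comparison,
    partial-volume-effect boundary-pixel correction, and synthetic voxel
    and 2D phantom generators with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
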