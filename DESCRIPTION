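Package: connmri
Title: Functional and Structural Connectivity Pipelines for Mouse Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Dual-modality connectivity analysis for small-animal MRI studies.
    A resting-state fMRI arm turns 4D BOLD volumes into ROI-wise Fisher-z
    functional-connectivity matrices via nuisance regression, in-plane Gaussian
    smoothing, band-pass filtering and per-voxel normalization, with intra-node
    strength, nonparametric edge-wise group statistics (Friedman,
    Kruskal-Wallis with Dunn post hoc) and an origin-constrained slope metric
    for longitudinal network change. A diffusion arm reconstructs analytic
    Q-ball orientation distribution functions with Laplace-Beltrami
    regularization, extracts quantitative-anisotropy peaks, runs deterministic
    streamline tractography and builds voxel-normalized fiber-density
    matrices. A synthetic-data module simulates multi-group two-time-point
    BOLD cohorts with known correlation structure and multi-tensor diffusion
    phantoms so every stage is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
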