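Package: vcgischemia
Title: Myocardial Ischemia Detection from ECG and Derived Vectorcardiogram ST-T Features
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for detecting myocardial ischemia from short (20 s) 12-lead
    electrocardiogram records. Implements baseline-drift removal with a
    zero-phase Butterworth high-pass filter, wavelet (coif4) denoising with
    universal soft thresholding, derivation of the 3-lead vectorcardiogram
    (VCG) via the Kors-style fixed linear lead transform, R-peak detection and
    ST-T segment delineation, and three feature families computed on spliced
    beat-to-beat ST-T series: per-lead sample entropy, a Lyapunov-style
    spatial heterogeneity index of the 3D VCG trajectory, and a spectral
    exponential-decay temporal heterogeneity index. Classification uses an
    RBF-kernel support vector machine with single-feature screening,
    exhaustive subset search, a PCA baseline with Minka dimension selection,
    and stratified 5-fold cross-validation. A synthetic-data generator
    provides labelled healthy/ischemic records so the full pipeline is
    testable without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
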