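Package: cardiocohere
Title: Brain-Heart Coherence Analysis for Naturalistic fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies moment-to-moment coherence between heart rate and
    brain activity during naturalistic (movie-watching) fMRI. Provides
    cardiac preprocessing (gap interpolation, Savitzky-Golay smoothing,
    TR-grid resampling with hemodynamic lag, Legendre detrending),
    nuisance residualization of BOLD data, Gaussian-kernel sliding-window
    dynamic connectivity, three brain-heart coherence estimators
    (Fisher-transformed bivariate correlation, band-constrained dynamic
    time warping, and voxel-wise cross-correlation maxima with lag maps),
    paired group inference with Bonferroni families and sign-flip
    permutation cluster-extent correction, and a synthetic-data generator
    with known, condition-dependent brain-heart coupling for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    RNifti,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
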