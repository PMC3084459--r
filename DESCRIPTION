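Package: krfmri
Title: Kernel Regression Decoding for fMRI Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate decoding of continuous stimulus ratings from 4D fMRI
    time series with kernel methods. Provides gray-matter masking, Gaussian
    spatial smoothing, discrete-cosine-transform high-pass detrending applied
    directly in kernel space through the residual-forming matrix, linear, RBF
    and polynomial kernels, kernel ridge regression, relevance vector
    regression with automatic relevance determination, Gaussian-process
    evidence maximisation of the ridge penalty, hemodynamic-response-aware
    post-processing (box-constrained deconvolution by quadratic programming,
    re-convolution, temporal smoothing and shifting, match-filter event
    insertion), Fisher r-to-z scoring with session-wise cross-validation, and
    a synthetic-data generator that emulates drifting, noisy, rating-driven
    BOLD volumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
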