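Package: noiseceiling
Title: Test-Data Noise Ceilings for Voxelwise fMRI Encoding Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the maximum attainable prediction accuracy
    ("test-data noise ceiling") of voxelwise computational models of fMRI
    responses.  Single-stimulus response amplitudes and their estimation
    variance are obtained by generalized least squares under i.i.d.,
    AR(1)-REML or non-stationary (per-volume weighted) noise models, or
    non-parametrically from the run-to-run variability of per-run estimates.
    The ceiling is computed analytically from the signal/noise variance
    decomposition of the estimated responses, by Monte Carlo resampling, or
    by the Spearman-Brown corrected split-half correlation.  Linearized
    encoding models are fit by ridge regression and scored with correlation,
    predictive R-squared and squared Euclidean distance.  A simulation
    engine generates fMRI time series with known ground truth under four
    noise scenarios and validates every estimator against the true ceiling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
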