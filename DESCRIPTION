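Package: dspline
Title: Improved Discriminative Spatial Patterns for Event-Related EEG Classification
Version: 0.1.0
Authors@R: person("dspline", "maintainers", email = "dspline@example.org", role = c("aut", "cre"))
Description: Feature extraction and single-trial classification of event-related
    EEG epochs using discriminative spatial patterns (DSP). Implements the
    classic generalized-eigenproblem DSP as an oracle backend and an improved
    closed-form variant that computes per-class Fisher discriminant directions
    without an eigendecomposition, avoiding the complex-eigenvalue failure mode
    of the naive formulation. Includes ERP component windowing (N70, P120,
    N170-P200, P300, P400-700), zero-phase Butterworth band filtering,
    amplitude-threshold artifact rejection, baseline correction, sequential
    forward feature selection, k-nearest-neighbour classification under
    repeated stratified cross-validation, frequency-band feature fusion, a
    synthetic three-condition ERP generator with known ground truth, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
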