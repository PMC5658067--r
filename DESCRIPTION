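Package: slowbold
Title: Slow Calcium Wave Detection and Event-Related BOLD Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline relating optically recorded slow
    oscillation-associated calcium waves to whole-brain BOLD fMRI.
    Implements exponential-moving-average (EMA) based slow-wave event
    detection in fiber-photometry traces, model-free finite impulse
    response (FIR) extraction of the hemodynamic response to wave onsets,
    gamma-variate response quantification (time-to-peak, normalized peak
    amplitude, half-maximum duration), event-related general linear model
    mapping with AR(1) prewhitening, seed-based and calcium-informed
    correlation mapping with cluster-extent filtering, and specificity
    controls (time-mirrored and session-swapped event regressors).
    Includes a synthetic-data generator producing paired calcium traces
    and 4D BOLD sessions with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    minpack.lm,
    nortest,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
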