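Package: axiomerf
Title: Axiomatic Tests for Reward Prediction-Error Signals in
    Event-Related M/EEG Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for testing whether an event-related M/EEG sensor signal
    behaves like a reward prediction error under the axiomatic (Caplin-Dean)
    criteria.  Simulates gambling-task sessions with known evoked components
    and realistic noise; preprocesses epoched sensor data (zero-phase
    Butterworth filtering, resampling, baseline correction, amplitude-based
    artifact rejection, signal-space projection of eye blinks, mastoid
    re-referencing, robust trial averaging); converts condition averages into
    smoothed two-dimensional scalp-by-time image volumes; fits mass-univariate
    ANCOVA models with parametric outcome-probability modulators, with peak
    and cluster-extent thresholding and an inclusive mask derived from
    fully-predicted outcomes; and runs the axiomatic compliance battery
    together with feedback-related negativity (FRN) difference-wave analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
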