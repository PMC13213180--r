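Package: recruitcurve
Title: H-Reflex and M-Wave Recruitment-Curve Analysis at Reduced EMG
    Sampling Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating, preprocessing and analysing H-reflex and
    M-wave recruitment-curve EMG recordings, with an emphasis on how reduced
    sampling rates (as found in portable EEG/EMG acquisition systems) affect
    the stimulation-intensity parameters derived from the fitted curves.
    Includes a synthetic-EMG generator with known ground-truth recruitment
    functions, Butterworth filtering and anti-aliased integer downsampling
    with trigger quantisation, stimulus-artifact blanking and exponential
    decay removal, manual and automated response-window delineation,
    sigmoid and hill-curve (product of two sigmoids) recruitment-curve
    fitting with target-intensity extraction, and a method-agreement
    statistical battery (Friedman test with Kendall's w, Tukey post hoc on
    ranks, absolute-agreement ICC, TOST equivalence, Bland-Altman limits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
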