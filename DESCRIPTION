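Package: saswave
Title: Wavelet Phase Coherence Analysis of Subarachnoid Space and Blood
    Pressure Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Resting-state time-frequency analysis of subarachnoid-space
    (SAS) width and blood-pressure (BP) recordings: Morlet continuous
    wavelet transforms on a logarithmic frequency grid (0.005-2 Hz),
    time-averaged spectra summarised over six physiological frequency
    intervals (cardiac, respiratory, myogenic, neurogenic and two
    endothelial bands), wavelet phase coherence with circular-mean phase
    differences, intersubject-surrogate significance thresholds,
    nonparametric cohort comparisons with an effect-size/power gate, and a
    seeded synthetic cohort generator so the full pipeline can be
    validated end to end without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
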