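Package: wavepoch
Title: Wavelet-Based Detection of Transient Oscillation Epochs in
    Extracellular Field Recordings
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and characterization of infrequent, brief,
    low-amplitude oscillation epochs in local field potential recordings
    such as those obtained from multielectrode arrays. Implements a
    continuous Morlet wavelet detector with histogram-based adaptive
    thresholding on an octave-spaced frequency grid, three comparator
    methods (averaged power spectral density with a peak test, short-time
    Fourier transform detection, and amplitude-envelope thresholding), a
    1/f-noise simulation benchmark with embedded sinusoidal epochs and
    ground truth, and downstream band metrics: epoch rates and durations,
    the low:high frequency epoch-number ratio, cross-frequency
    phase-amplitude coupling with surrogate testing, effect sizes and
    condition-comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
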