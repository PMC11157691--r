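Package: opmloop
Title: Real-Time Model-Based Magnetic Field Correction for Wearable OPM-MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and evaluating real-time homogeneous field
    correction (HFC) for optically pumped magnetometer (OPM) MEG arrays.
    Models the background magnetic field across a rigid sensor array with
    low-order regular solid harmonics, forms the feedback and denoising
    projectors from the array geometry, and simulates the closed feedback
    loop including chunked averaging, streaming biquad low-pass filtering,
    DAC quantization, command latency and jitter, sensor saturation and
    coil cross-talk. Includes a synthetic scenario generator (drifting and
    spatially varying room fields, walking trajectories with motion-capture
    dropouts, roving-oddball auditory stimulation and evoked responses),
    an amplitude-histogram saturation detector with trial rejection, and
    evaluation statistics (Welch amplitude spectral densities, the median
    shielding factor, epoched evoked averages and t-statistic SNR ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
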