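Package: preycapture
Title: Kinematic and Closed-Loop Analysis of Zebrafish Larval Prey-Capture Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies larval zebrafish prey-capture behavior from
    high-speed dark-field video. Provides a synthetic generator of bout
    kinematics, rendered video and tail-sensor traces with exact ground
    truth; an image pipeline extracting the six-segment midline (heading
    and five tail-segment angles), eye angles and fish-prey geometry; a
    spectral decomposition of swim bouts into single-sided RMS amplitude
    spectra with low- and high-frequency peaks and a signed Direction
    Index; sequence-level statistics (inter-bout intervals, folded angle
    histograms, reflected straight-line fits, two-step eye-convergence
    sequence classification); and a discrete-event simulation of a
    closed-loop virtual-reality stimulus paradigm with update-location,
    update-delay and size/velocity escalation protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    stats,
    jsonlite,
    png,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
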