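Package: optoresp
Title: Analysis of Optogenetically Evoked Responses in Extracellular and
    Voltage-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying neuronal responses to brief optogenetic
    stimuli. Builds peristimulus time histograms (PSTHs) from sorted spike
    times and stimulus markers, detects evoked excitation and inhibition
    against baseline-derived thresholds, classifies units as excited,
    excited-then-inhibited, inhibited or non-responsive, and computes the
    extra-spikes statistic, 20-Hz train-following profiles and graded
    light-power response curves. A companion voltage-clamp module measures
    evoked EPSC amplitudes and short-term depression from current sweeps.
    Includes an inhomogeneous-Poisson spike-train and synthetic sweep
    generator with known ground truth for parameter-recovery testing, and
    plain-text readers/writers for spike trains, stimulus protocols and
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
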