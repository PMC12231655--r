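Package: setms
Title: Beat-Locked TMS Scheduling and EEG/EMG Analysis for Sensory
    Entrained Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for sensory entrained transcranial magnetic stimulation
    (seTMS) experiments: metronome and beat-schedule construction with
    TMS pulse timing locked to auditory strong beats, Morlet-wavelet
    time-frequency decomposition with event-related spectral perturbation
    and intertrial coherence (ITC), extraction of the pre-beat alpha-ITC
    trough / post-beat peak / slope statistic, a motor-evoked-potential
    (MEP) preprocessing and peak-to-peak quantification chain with
    rejection audit and condition statistics, and a calibrated synthetic
    EEG/EMG cohort generator with known ground truth for end-to-end
    validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
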