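Package: usvwhisk
Title: Coordination of Ultrasonic Vocalization, Whisking and Auditory
    Cortex Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for rodent social-touch experiments that
    combine ultrasonic vocalization (USV) recordings, high-speed whisker
    tracking and auditory-cortex single-unit electrophysiology. Provides
    whisking-phase decomposition (band-pass filtering, cycle detection and
    quality control, analytic-signal phase), microphone-array call-source
    assignment with accuracy accounting, call-whisking coordination
    statistics (Hodges-Ajne uniformity test, call-triggered whisking
    averages, retraction/protraction splits), regular-/fast-spiking unit
    classification from spike-waveform widths, response indices against
    matched event-free baselines, and spike-whisking phase locking with a
    count-insensitive circular time-shift shuffle test. A synthetic-session
    generator with known ground-truth coupling supports calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
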