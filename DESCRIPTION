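Package: callprop
Title: Playback Propagation Experiments and Excess Attenuation of Anuran Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sound-transmission playback experiments in bioacoustics:
    synthesis of calibrated playback stimuli (pure-tone series, synthetic anuran
    advertisement calls, white noise, calibration tones), simulation of
    propagation transects over water and soil substrates with known
    frequency-dependent attenuation, calibration-referenced sound pressure
    level measurement, excess attenuation relative to spherical spreading with
    linear-scale decibel averaging, and four-way repeated-measures ANOVA with
    Mauchly sphericity diagnostics and Huynh-Feldt corrected p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
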