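Package: airleakr
Title: Sound-Guided Assessment and Localization of Pulmonary Air Leaks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative analysis of pulmonary air-leak sounds recorded near
    the lung surface during positive-pressure ventilation. Provides A-weighted
    sound pressure level computation, spectrogram and plateau power-spectrum
    analysis, detection of harmonic frequency bands and their regression on
    frequency, breath segmentation from airway-pressure traces,
    pressure-loudness correlation, leak-severity grading, and leak-site
    localization from a microphone-grid sound intensity matrix. Includes a
    seeded synthetic acoustic-scene generator (ventilator pressure waveforms,
    pressure-modulated harmonic leak sources, sub-400 Hz heart sounds, ambient
    noise, distance attenuation over a 1 cm grid) so that every analysis stage
    is verifiable against known ground truth without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
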