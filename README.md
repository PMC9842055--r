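# airleakr

Quantitative, sound-guided assessment and localization of pulmonary air
leaks from intrapleural microphone recordings synchronized with airway
pressure.

Air leaks — air escaping the lung through a pleural defect, most often a
failed surgical staple — are the most common complication of lung surgery,
and current clinical tools can neither grade them objectively nor locate
them precisely. Air escaping under positive-pressure ventilation makes the
surrounding pleural tissue oscillate, radiating a distinctive sound whose
spectrum is a **harmonic series**: narrow bands at integer multiples `k·f0`
of a fundamental set by the defect, with peak band power falling roughly
linearly with frequency (`Y = a·X + b` in dB vs Hz). Loudness (A-weighted
SPL) tracks airway pressure within each breath and grows with the leak's
volume loss, and it decays with distance from the defect — so a grid of
short recordings over the lung surface, normalized to its maximum, peaks at
the leak site.

`airleakr` is for researchers and engineers working on acoustic diagnostics
of respiratory air leaks. It provides:

* **audio/pressure I/O** — mono WAV (PCM16/24, float32), airway-pressure CSV;
* **DSP** — A-weighted SPL series, spectrograms, Welch power spectra
  (dB re full scale, full-scale sine = 0 dB), zero-phase Butterworth
  high-pass (500 Hz default) for heart-sound removal, mixing, spectral
  density histograms;
* **band analysis** — band detection with −80/−60 dB presets,
  harmonic-number assignment (ratio tolerance 0.25), harmonic-series
  identification that excludes non-harmonic ventilator bands, band-power
  regression with `tidy()`/`glance()` methods;
* **breath analysis** — prominence-based breath segmentation, inspiratory
  plateau extraction (≥ 90% of peak pressure), pressure–loudness Pearson
  correlation on a common 20 Hz grid, per-phase loudness slopes, calibrated
  severity grading;
* **localization** — per-cell mean loudness, power-domain normalization to
  0–1, argmax leak location with tie handling and Euclidean error;
* **a seeded synthetic scene generator** (ventilator waveforms,
  pressure-modulated harmonic leaks, sub-400 Hz heart sounds, ambient noise,
  1/r grid attenuation) providing ground truth for every stage.

Functions take data frames / tibbles first and return tibbles, so results
chain with the pipe; each result type has an `autoplot()` method.

## Worked example

Generate a human-scale (swine-regime) leak scene and assess it:

```r
library(airleakr)

sc  <- gen_scene(swine_scene_config(seed = 1))
rep <- assess_recording(sc$audio, sc$truth$pressure, preset = "swine")
rep
#> <leak_assessment>
#>   SPL: 39.9-51.7 dBA (plateau 51.6, baseline 40.3)
#>   pressure-SPL correlation rho = 0.988
#>   2 breaths, 4 bands, f0 = 664 Hz (harmonics 1,2,3,4)
#>   band power: Y = -0.0079764X -34.61, R2 = 1.00
#>   severity: mild
```

Reading the report: loudness swings ~12 dBA between the expiratory floor and
the inspiratory plateau and correlates with airway pressure at ρ = 0.99;
the plateau spectrum contains four bands forming a harmonic series on a
665 Hz fundamental; band power falls at −0.008 dB/Hz; and the plateau level
(51.6 dBA re the default calibration) grades as a mild leak. All numbers
match the generator's configuration (`f0` within one FFT bin, regression on
the configured −0.00792 dB/Hz law within 1%).

Localize a leak from a simulated 5×5, 1 cm microphone grid at 10 dB SNR:

```r
g   <- gen_grid_recordings(swine_scene_config(duration_s = 5, seed = 1),
                           n_rows = 5, n_cols = 5, leak_cell = c(3, 3),
                           standoff_cm = 1, snr_db = 10)
m   <- normalize_intensity(build_intensity_matrix(g$recordings))
loc <- locate_leak(m)
localization_error(loc, g$truth$position_cm)
#> [1] 0
autoplot(m)   # 0-1 heatmap, 1.00 at the leak cell
```

A thin command-line front-end wraps the same functions:

```sh
$(Rscript -e 'cat(system.file("cli", "airleak", package = "airleakr"))') \
  assess --wav scene.wav --pressure pressure.csv --preset swine --out report.json
```

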