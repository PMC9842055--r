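---
title: "Methods: sound-guided assessment and localization of pulmonary air leaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sound-guided assessment and localization of pulmonary air leaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airleakr)
```

## The problem

A pulmonary air leak is the escape of air from the lung airspaces through a
defect in the visceral pleura — typically a failed staple after lung
resection — into the pleural space. Escaping air transfers kinetic energy to
the surrounding pleural tissue, which oscillates at its resonance frequency
and radiates sound, much as airflow through the glottis drives vocal-fold
phonation. Recorded close to the lung surface during positive-pressure
ventilation, these leak sounds carry three kinds of quantitative information:

* **Detection and structure.** The leak spectrum is a *harmonic series*:
  narrow frequency bands at integer multiples of a fundamental set by the
  defect geometry. In a small-animal (rat) setting the fundamental sits near
  1223 Hz with harmonics up to the 7th (the 6th is absent), plus a louder
  non-harmonic band near 890 Hz traced to the ventilator; in a human-scale
  (swine) setting the fundamental is lower (665 Hz, harmonics 1–4), because
  oscillation frequency falls with defect size. Band intensity declines
  approximately linearly with frequency.
* **Severity.** Leak loudness rises and falls with airway pressure within
  each breath; its plateau level grows with the air volume lost per breath,
  so calibrated loudness grades severity.
* **Location.** Loudness decays monotonically with distance from the defect,
  so a grid of short recordings over the lung surface, normalized to its
  maximum, peaks at the leak site with resolution of about one grid step.

`airleakr` implements the full chain — loudness, spectra, band and harmonic
analysis, breath segmentation, correlation, severity grading, grid
localization — together with a seeded synthetic scene generator so that every
stage can be verified against known ground truth without animal recordings.

## Loudness and the dB convention

Microphone recordings arrive uncalibrated, so all spectral quantities are
expressed in **dB re digital full scale**, with the convention that a
full-scale sine reads 0 dB at its frequency bin (amplitude spectra are
normalized by `2/sum(window)`). Loudness adds a single configurable
`calibration_offset` (default 94 dB, i.e. full-scale RMS 1 maps to 94 dB
SPL), so absolute dBA is recovered once a calibrator tone is available. All
band-detection thresholds (−80 dB for the small-animal regime, −60 dB for
the large-animal regime) are on the full-scale-referenced scale and are
configuration values, not constants.

SPL uses **A-weighting**, the standard perceptual frequency weighting
normalized to 0 dB at 1 kHz. The weighting is applied in the frequency
domain using the exact closed-form analog magnitude (poles at 20.6, 107.7,
737.9 and 12194 Hz), rather than a bilinear-discretized IIR filter: the
bilinear warp distorts the response approaching Nyquist at common sampling
rates, while the spectral route reproduces the curve to machine precision at
every bin and is zero-phase by construction. The cost is block rather than
streaming operation, acceptable for file-based analysis.

SPL windows default to 125 ms with a 31.25 ms hop, following sound-level-
meter "fast" convention; the source recordings' own time weighting is not
documented, and the "fast" choice tracks within-breath loudness changes
without smearing the inspiratory rise.

## Spectra, bands and harmonics

Spectrograms and averaged (Welch) power spectra use Hann windows, 50%
overlap, and an FFT length defaulting to 4096 samples capped by the analysis
window — about 5 Hz resolution at the rates used here, comfortably resolving
bands spaced ≥ 665 Hz apart.

Band detection takes the averaged spectrum of the **inspiratory plateau**
(see below), finds strict local maxima above the threshold in the configured
range (0–10 kHz small-animal, 0–5 kHz large-animal), and merges peaks closer
than `min_separation_hz` (default 200 Hz), keeping the stronger. Band
centers are power-weighted centroids of the −3 dB neighborhood; peak levels
are refined by parabolic interpolation of the log-spectrum, which cancels
most of the Hann scalloping loss (worst case ~1.4 dB raw, < 0.2 dB after
interpolation).

A band at frequency `f` is an integer harmonic of fundamental `f0` when
`|f/f0 − round(f/f0)| ≤ tolerance` with default tolerance 0.25 — the
smallest value that accepts the observed ratios (e.g. 8845/1223 = 7.23).
The **fundamental is chosen by explanatory power**, not loudness: the
candidate band whose integer multiples explain the most bands wins, with
ties going to the lowest frequency. This matters because in the small-animal
regime the loudest and lowest band (890 Hz) is ventilator noise, not the
fundamental; it explains only 4 of 7 bands, while 1223 Hz explains 6, and
the 890 Hz band lands in the `excluded` set. Harmonic numbers may skip
integers (the small-animal series has no 6th harmonic); duplicate
assignments keep the best-fitting band. Band power is then regressed on band
frequency by ordinary least squares (`stats::lm`), reported with `tidy()`
and `glance()` methods.

## Breaths, correlation, phases, severity

Breaths are segmented from the airway-pressure trace by peak **prominence**
(default 2 cmH2O), with breath boundaries at the pressure minima between
consecutive peaks. The inspiratory plateau is defined reproducibly as the
contiguous run of samples at or above 90% of that breath's peak pressure —
a surrogate for the visually marked plateau region in the source protocol.
A triangular waveform (no plateau phase) degenerates gracefully to a plateau
of at most a few samples.

Pressure and SPL are compared after linear interpolation to a common 20 Hz
grid over their overlap and min-max normalization to 0–1 (making the Pearson
correlation invariant to affine rescaling of either series). 20 Hz sits
above breathing rates yet below the SPL hop rate, so neither series is
aliased. Phase slopes are per-breath OLS slopes of SPL against time over
inspiration (start → pressure peak) and expiration (peak → end), averaged
across breaths.

Severity is **calibrated, not absolute**: the published dBA-to-volume-loss
pairs come from one experimental setup, so the cut-points (mild < 58 dBA,
moderate 58–65, severe ≥ 65, detection margin 3 dBA above baseline) ship as
a documented, overridable preset. A level exactly at a cut-point goes to the
higher class — the conservative direction for a clinical alarm. The tested
contract is ordinal: plateau SPL, and hence the class, is monotone in the
generator's leak strength. Volume loss in ml/breath is accepted from
ventilator data only, never inferred from audio.

## Localization

Each grid cell's recording contributes its mean A-weighted SPL over the
first 5 s. Normalization divides **linear acoustic power** (not dB) by the
maximum cell power, reproducing the published 0–1 heatmap scale exactly
(maximum exactly 1.00) and making scores invariant to any global gain. The
leak estimate is the argmax cell; exact ties break toward the smallest
(row, col) and are flagged. Grids must be complete — missing cells are
refused rather than interpolated, since interpolation could fabricate a
hotspot. A near-uniform normalized matrix (spread below 0.1) raises a
no-leak flag; ambient-only simulations give spreads ≤ 0.05.

Coordinates follow the acquisition traversal: origin at the upper-left cell,
x rightward along columns, y downward along rows, cell centers at integer
multiples of the step (1 cm default).

## The synthetic scene generator

The generator is first-class, tested code; its defaults *are* the study
conditions:

* **Ventilation**: piecewise breath waveform — linear rise to PIP over
  `rise_fraction` of the period, plateau hold, exponential decay to PEEP.
  Small-animal preset: 70 bpm, PIP 16.2 cmH2O, PEEP 2. Large-animal preset:
  15 bpm, PEEP 5 cmH2O, PIP 20 — PIP is not printed in the source material;
  20 cmH2O is typical for swine positive-pressure ventilation and consistent
  with the reported driving pressure of ~20 cmH2O.
* **Leak**: sum of sines at `k · f0` with per-band amplitudes placed exactly
  on the configured power law (small-animal: −0.00231 dB/Hz, intercept
  −49.1 dB, harmonics {1,2,3,4,5,7}; large-animal: −0.00792 dB/Hz, −34.8 dB,
  harmonics 1–4), amplitude-modulated by the normalized driving pressure
  `max(0, P(t) − P_amb)^e`. The true pressure-to-loudness law is unknown
  (the source data show correlation, not a functional form), so the exponent
  `e` is a configuration knob with default 1 — the simplest monotone
  coupling, which reproduces the observed strong positive pressure-SPL
  correlation (ρ ≳ 0.99 on low-noise scenes).
* **Ventilator tone**: a stationary 890 Hz sine at −48 dB in the
  small-animal preset, louder than the leak fundamental, providing the
  realistic non-harmonic distractor the exclusion logic must handle.
* **Heart**: per beat, two Gaussian-windowed tone bursts (S1 120 Hz, S2
  90 Hz at 0.8× amplitude 0.3 s later, burst 60 ms). A Gaussian burst of
  time sd σ_t has spectral sd `1/(2π σ_t)` ≈ 16 Hz, so all power above
  −60 dB re peak lies below ~180 Hz — comfortably under the 400 Hz bound that
  makes 500 Hz high-pass separation work; configurations that would violate
  the bound are rejected at construction.
* **Ambient**: Gaussian white noise at a configured RMS level (−70 dB
  default, ≈ 20 dB below the leak plateau).
* **Grid**: leak amplitude scales as `standoff / r` (spherical spreading
  with a near-field floor at the 1 cm microphone standoff), `r` the
  Euclidean source-to-microphone distance; per-cell independent noise at a
  configured SNR re the loudest cell. No propagation model is stated in the
  source; 1/r is the simplest physically motivated monotone choice, and
  localization by argmax needs only monotone decay.

Determinism: every random draw (harmonic phases, tone phases, ambient noise,
per-cell noise) derives from the scene seed, so identical configurations
produce bit-identical audio.

**What the generator does not emulate** — and therefore what passing tests do
not show about real data: broadband turbulent flow noise and normal breath
sounds, bubble-burst transients, time-varying fundamentals within a breath,
room reverberation and correlated equipment noise, microphone directivity,
and tissue-dependent attenuation. Results on synthetic scenes validate the
*algorithms* against their stated contracts, not clinical performance.

## Numerical choices and degenerate inputs

* Problem sizes: preset scenes are 4 s at 22.05 kHz (small-animal) and 8 s
  at 16 kHz (large-animal); grid simulations use 5 s per cell on 5×5 grids,
  20 replicate seeds. These sizes keep every analysis deterministic and
  desk-scale while leaving ≥ 2 breaths and ≥ 4 plateau windows per scene.
* Silent windows clamp at a −120 dB floor before the calibration offset, so
  SPL series stay finite.
* Degenerate regressions are explicit: < 3 bands and identical frequencies
  are errors; exactly flat power returns slope 0 with R² = 0 rather than a
  0/0.
* A flat pressure trace (no ventilation) yields no breaths; the assessment
  pipeline then degrades to whole-recording statistics, reports severity
  from overall loudness, and flags the undefined correlation rather than
  failing.
* WAV support is deliberately narrow — mono PCM16/PCM24/float32, integers
  normalized by full scale — with multi-channel input refused unless channel
  averaging is requested explicitly.
* Resampling is Fourier-domain band-limited interpolation: tone frequencies
  below both Nyquist limits are preserved within one FFT bin and duration
  within one sample period.

## Known limitations

The severity scale transfers only as far as its calibration does; absolute
dBA depends on the microphone chain. Localization assumes one dominant
source and monotone attenuation — multiple simultaneous leaks, strongly
anisotropic propagation, or an incomplete grid defeat the argmax rule (the
latter by design). The harmonic-series search assumes at least `min_members`
bands from one series; two interleaved series from two defects would be
reported as one series plus exclusions. Fundamentals are assumed stable
across the analysis window; time-varying pitch tracking is out of scope.
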