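# Signal-processing core: A-weighting, loudness (SPL), spectrogram, averaged
# power spectrum, high-pass filtering, mixing.
#
# dB convention used throughout: recordings are uncalibrated, so spectral
# levels are expressed in dB re digital full scale with a full-scale sine
# mapping to 0 dB (amplitude spectra are normalized by 2/sum(window)).
# Loudness adds a configurable calibration offset (default 94 dB, i.e. a
# full-scale RMS of 1 corresponds to 94 dB SPL) so absolute dBA can be
# recovered when a calibrator is available.

# periodic Hann window (DFT-even), constant-sum normalization via sum(w)
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' A-weighting gain at a frequency
#'
#' Evaluates the standard A-weighting curve (the closed-form analog transfer
#' function with poles at 20.6, 107.7, 737.9 and 12194 Hz), normalized to
#' exactly 0 dB at 1 kHz.
#'
#' @param frequency Frequency in Hz (> 0); vectorized.
#' @return Gain in dB (negative = attenuation).
#' @examples
#' a_weighting_gain(c(100, 1000, 10000))
#' @export
a_weighting_gain <- function(frequency) {
  abort_if(!is.numeric(frequency) || any(!is.finite(frequency)) || any(frequency <= 0),
           "`frequency` must be positive and finite", class = "airleakr_argument_error")
  ra <- function(f) {
    (12194^2 * f^4) /
      ((f^2 + 20.6^2) * sqrt((f^2 + 107.7^2) * (f^2 + 737.9^2)) * (f^2 + 12194^2))
  }
  20 * log10(ra(frequency)) - 20 * log10(ra(1000))
}

#' Apply A-weighting to a waveform
#'
#' The A-curve is applied in the frequency domain (exact analog magnitude,
#' zero phase), so the output spectrum equals the input spectrum shaped by
#' [a_weighting_gain()] at every bin; DC is removed.
#'
#' @param segment An [audio_segment()].
#' @return The A-weighted [audio_segment()].
#' @export
apply_a_weighting <- function(segment) {
  stopifnot(inherits(segment, "audio_segment"))
  n <- length(segment$samples)
  if (all(segment$samples == 0)) return(segment)
  freqs <- (seq_len(n) - 1) / n * segment$sample_rate
  freqs <- pmin(freqs, segment$sample_rate - freqs)   # fold to 0..Nyquist
  gain <- numeric(n)
  pos <- freqs > 0
  gain[pos] <- 10^(a_weighting_gain(freqs[pos]) / 20)
  y <- Re(fft(fft(segment$samples) * gain, inverse = TRUE)) / n
  audio_segment(y, segment$sample_rate, segment$start_time)
}

#' A-weighted sound pressure level series
#'
#' Short-time loudness: the segment is A-weighted, then the RMS of each
#' analysis window is converted to dB and offset by the calibration constant,
#' `level = 20*log10(rms) + calibration_offset`. Window and hop defaults
#' follow sound-level-meter "fast" convention (125 ms window).
#'
#' @param segment An [audio_segment()].
#' @param window_s Analysis window in seconds (>= `hop_s`).
#' @param hop_s Hop between windows in seconds (> 0).
#' @param calibration_offset dB added to full-scale-referenced levels
#'   (default 94: full-scale RMS of 1 maps to 94 dB SPL).
#' @param a_weight Apply A-weighting first (default `TRUE`).
#' @param floor_db Lower clamp on the pre-offset level, so silent windows stay
#'   finite.
#' @return An `spl_series` tibble with columns `time_s` (window centers) and
#'   `dba`, carrying `window_s`, `hop_s` and `calibration_offset` attributes.
#' @export
spl_series <- function(segment, window_s = 0.125, hop_s = 0.03125,
                       calibration_offset = 94, a_weight = TRUE,
                       floor_db = -120) {
  stopifnot(inherits(segment, "audio_segment"))
  check_number(window_s, "window_s", positive = TRUE)
  check_number(hop_s, "hop_s", positive = TRUE)
  abort_if(window_s < hop_s, "`window_s` must be >= `hop_s`",
           class = "airleakr_argument_error")
  rate <- segment$sample_rate
  wn <- max(2L, as.integer(round(window_s * rate)))
  hop <- max(1L, as.integer(round(hop_s * rate)))
  abort_if(length(segment$samples) < wn,
           "segment shorter than one analysis window",
           class = "airleakr_argument_error")
  x <- if (a_weight) apply_a_weighting(segment)$samples else segment$samples
  cs <- c(0, cumsum(x^2))
  starts <- seq(1L, length(x) - wn + 1L, by = hop)
  rms <- sqrt((cs[starts + wn] - cs[starts]) / wn)
  level <- pmax(20 * log10(pmax(rms, 1e-300)), floor_db) + calibration_offset
  out <- tibble(
    time_s = segment$start_time + (starts - 1L + wn / 2) / rate,
    dba = level
  )
  attr(out, "window_s") <- wn / rate
  attr(out, "hop_s") <- hop / rate
  attr(out, "calibration_offset") <- calibration_offset
  class(out) <- c("spl_series", class(out))
  out
}

# short-time Fourier transform shared by spectrogram() and power_spectrum():
# returns list(times [window centers], frequencies, amp2 [time x freq linear
# power, full-scale sine = 1])
stft_power <- function(segment, n_fft, overlap_fraction) {
  x <- segment$samples
  rate <- segment$sample_rate
  hop <- max(1L, as.integer(round(n_fft * (1 - overlap_fraction))))
  abort_if(length(x) < n_fft, "window longer than signal",
           class = "airleakr_argument_error")
  starts <- seq(1L, length(x) - n_fft + 1L, by = hop)
  w <- hann_window(n_fft)
  scale <- 2 / sum(w)
  n_bins <- n_fft %/% 2L + 1L
  amp2 <- vapply(starts, function(s) {
    X <- fft(x[s:(s + n_fft - 1L)] * w)
    (scale * Mod(X[seq_len(n_bins)]))^2
  }, numeric(n_bins))
  list(
    times = segment$start_time + (starts - 1L + n_fft / 2) / rate,
    frequencies = (seq_len(n_bins) - 1) * rate / n_fft,
    amp2 = t(amp2)   # time x frequency
  )
}

#' Spectrogram of an audio segment
#'
#' Short-time power in dB re full scale (full-scale sine = 0 dB at its bin),
#' Hann-windowed, clipped below at `floor_db`.
#'
#' @param segment An [audio_segment()].
#' @param window_s Window length in seconds (default 92.9 ms, 4096 samples at
#'   44.1 kHz, resolving harmonic bands ~10 Hz apart).
#' @param overlap_fraction Fractional window overlap in `[0, 1)`.
#' @param floor_db Display floor in dB.
#' @return A `leak_spectrogram` object with fields `time_s`, `frequency_hz`
#'   and `power_db` (time x frequency matrix).
#' @export
spectrogram <- function(segment, window_s = 0.0929, overlap_fraction = 0.5,
                        floor_db = -100) {
  stopifnot(inherits(segment, "audio_segment"))
  abort_if(overlap_fraction < 0 || overlap_fraction >= 1,
           "`overlap_fraction` must be in [0, 1)", class = "airleakr_argument_error")
  n_fft <- max(16L, as.integer(round(window_s * segment$sample_rate)))
  st <- stft_power(segment, n_fft, overlap_fraction)
  structure(
    list(time_s = st$times, frequency_hz = st$frequencies,
         power_db = pmax(10 * log10(pmax(st$amp2, 1e-300)), floor_db),
         window_s = n_fft / segment$sample_rate,
         overlap_fraction = overlap_fraction, floor_db = floor_db),
    class = "leak_spectrogram"
  )
}

#' @export
print.leak_spectrogram <- function(x, ...) {
  cat(sprintf("<leak_spectrogram: %d windows x %d bins, %.1f-%.1f Hz, window %.1f ms>\n",
              length(x$time_s), length(x$frequency_hz), min(x$frequency_hz),
              max(x$frequency_hz), 1000 * x$window_s))
  invisible(x)
}

#' @export
as_tibble.leak_spectrogram <- function(x, ...) {
  tidyr::expand_grid(time_s = x$time_s, frequency_hz = x$frequency_hz) |>
    dplyr::mutate(power_db = as.vector(t(x$power_db)))
}

#' Averaged power spectrum of a time window
#'
#' Welch-style averaged periodogram (Hann windows, 50% overlap) of the chosen
#' window, in dB re full scale: a full-scale sine at a bin center reads 0 dB.
#'
#' @param segment An [audio_segment()].
#' @param t0,t1 Window limits in seconds; defaults cover the whole segment.
#' @param n_fft FFT length; defaults to the largest power of two up to 4096
#'   that fits in the window.
#' @return A `power_spectrum` tibble with columns `frequency_hz`, `power_db`
#'   and a `source_window` attribute.
#' @export
power_spectrum <- function(segment, t0 = NULL, t1 = NULL, n_fft = NULL) {
  stopifnot(inherits(segment, "audio_segment"))
  t0 <- t0 %||% segment$start_time
  t1 <- t1 %||% (segment$start_time + duration(segment))
  seg <- crop(segment, t0, t1)
  n <- length(seg$samples)
  if (is.null(n_fft)) n_fft <- min(4096L, 2L^max(4L, floor(log2(n))))
  abort_if(n_fft > n, "window [", t0, ", ", t1, "] too short for n_fft = ", n_fft,
           class = "airleakr_argument_error")
  st <- stft_power(seg, n_fft, 0.5)
  mean_amp2 <- colMeans(st$amp2)
  out <- tibble(
    frequency_hz = st$frequencies,
    power_db = 10 * log10(pmax(mean_amp2, 1e-300))
  )
  attr(out, "source_window") <- c(t0, t1)
  attr(out, "n_fft") <- n_fft
  attr(out, "sample_rate") <- seg$sample_rate
  class(out) <- c("power_spectrum", class(out))
  out
}

#' Zero-phase Butterworth high-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, the operation used to
#' strip sub-400 Hz heart sounds from leak recordings with a 500 Hz cutoff.
#' Two passes double the attenuation: the response is 6 dB down at the cutoff.
#'
#' @param segment An [audio_segment()].
#' @param cutoff_hz Cutoff frequency (0 < cutoff < Nyquist). Default 500 Hz.
#' @param order Butterworth order of the single-pass design (default 4).
#' @return The filtered [audio_segment()].
#' @export
highpass <- function(segment, cutoff_hz = 500, order = 4) {
  stopifnot(inherits(segment, "audio_segment"))
  check_number(cutoff_hz, "cutoff_hz", positive = TRUE)
  abort_if(cutoff_hz >= segment$sample_rate / 2,
           "`cutoff_hz` must be below the Nyquist frequency (",
           segment$sample_rate / 2, " Hz)", class = "airleakr_argument_error")
  bf <- signal::butter(order, cutoff_hz / (segment$sample_rate / 2), type = "high")
  y <- signal::filtfilt(bf, segment$samples)
  audio_segment(y, segment$sample_rate, segment$start_time)
}

#' Mix two audio signals
#'
#' Sample-wise weighted sum `gain_a * a + gain_b * b`; signals are cropped to
#' the shorter length, and the mixture is peak-normalized only if it would
#' clip.
#'
#' @param a,b [audio_segment()]s with equal sample rates.
#' @param gain_a,gain_b Linear gains.
#' @return The mixed [audio_segment()] (start time taken from `a`).
#' @export
mix_signals <- function(a, b, gain_a = 1, gain_b = 1) {
  stopifnot(inherits(a, "audio_segment"), inherits(b, "audio_segment"))
  abort_if(a$sample_rate != b$sample_rate,
           "sample rates differ (", a$sample_rate, " vs ", b$sample_rate, ")",
           class = "airleakr_argument_error")
  n <- min(length(a$samples), length(b$samples))
  y <- gain_a * a$samples[seq_len(n)] + gain_b * b$samples[seq_len(n)]
  peak <- max(abs(y))
  if (peak > 1) y <- y / peak
  audio_segment(y, a$sample_rate, a$start_time)
}

#' Histogram of spectral power density
#'
#' Bins the per-frequency power values of a spectrum into dB-wide classes;
#' the count total equals the number of frequency bins regardless of bin
#' width. Comparing this histogram before and after high-pass filtering shows
#' the removed low-frequency (heart-sound) mass.
#'
#' @param spectrum A [power_spectrum()].
#' @param bin_db Histogram bin width in dB (> 0).
#' @return A tibble with columns `bin_low_db`, `bin_high_db`, `count`.
#' @export
power_density_histogram <- function(spectrum, bin_db = 5) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  check_number(bin_db, "bin_db", positive = TRUE)
  abort_if(nrow(spectrum) == 0, "empty spectrum", class = "airleakr_argument_error")
  p <- spectrum$power_db
  lo <- floor(min(p) / bin_db) * bin_db
  breaks <- seq(lo, max(p) + bin_db, by = bin_db)
  counts <- tabulate(findInterval(p, breaks, rightmost.closed = FALSE),
                     nbins = length(breaks) - 1L)
  tibble(
    bin_low_db = breaks[-length(breaks)],
    bin_high_db = breaks[-1],
    count = counts
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
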