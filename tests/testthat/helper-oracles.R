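# Shared fixtures and independent oracles, built in code at test time.

# pure tone segment
tone <- function(freq, rate = 44100, dur = 1, amp = 1, phase = 0) {
  t <- seq(0, dur, by = 1 / rate)[-1]
  audio_segment(amp * sin(2 * pi * freq * t + phase), rate)
}

# dominant-frequency oracle: location of the periodogram maximum
fft_peak_hz <- function(segment) {
  x <- segment$samples
  n <- length(x)
  mag <- Mod(fft(x))[seq_len(n %/% 2 + 1)]
  (which.max(mag) - 1) * segment$sample_rate / n
}

# brute-force windowed-RMS SPL oracle, independent of spl_series() internals
brute_spl <- function(x, rate, window_s, hop_s, offset) {
  wn <- round(window_s * rate)
  hop <- round(hop_s * rate)
  starts <- seq(1, length(x) - wn + 1, by = hop)
  vapply(starts, function(s) {
    20 * log10(sqrt(mean(x[s:(s + wn - 1)]^2))) + offset
  }, numeric(1))
}

# closed-form simple-OLS oracle
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# RMS in dB of a segment's samples
rms_db <- function(segment) 20 * log10(sqrt(mean(segment$samples^2)))

# a synthetic power_spectrum object with Gaussian peaks on a flat floor
synthetic_spectrum <- function(peak_hz, peak_db, floor_db = -100,
                               df = 5, fmax = 11000, width_hz = 20) {
  f <- seq(0, fmax, by = df)
  p <- rep(floor_db, length(f))
  for (i in seq_along(peak_hz)) {
    p <- pmax(p, peak_db[i] - 3 * ((f - peak_hz[i]) / width_hz)^2)
  }
  out <- tibble::tibble(frequency_hz = f, power_db = p)
  attr(out, "source_window") <- c(0, 1)
  class(out) <- c("power_spectrum", class(out))
  out
}

# minimal hand-rolled stereo PCM16 WAV writer (the package itself is mono-only)
write_stereo_wav <- function(path, left, right, rate = 8000) {
  inter <- as.integer(round(as.vector(rbind(left, right)) * 32767))
  payload <- writeBin(inter, raw(), size = 2, endian = "little")
  con <- file(path, "wb"); on.exit(close(con))
  wr32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wr16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); wr32(36 + length(payload))
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wr32(16)
  wr16(1); wr16(2); wr32(rate); wr32(rate * 4); wr16(4); wr16(16)
  writeChar("data", con, eos = NULL); wr32(length(payload))
  writeBin(payload, con)
  path
}
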