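# In-memory audio representation and WAV file I/O.
#
# Recordings are mono waveforms with dimensionless amplitude (nominal range
# -1..+1, i.e. re digital full scale); absolute calibration is carried
# separately as a dB offset by the loudness functions.

#' Construct an audio segment
#'
#' An `audio_segment` is the uniformly sampled mono waveform consumed by all
#' signal-processing functions: a numeric amplitude vector (nominal range
#' −1..+1), a sample rate in Hz, and the start time of the first sample in
#' seconds.
#'
#' @param samples Numeric vector of amplitudes; must be finite and non-empty.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds.
#' @return An object of class `audio_segment`.
#' @examples
#' tone <- audio_segment(sin(2 * pi * 1000 * seq(0, 1, by = 1 / 8000)), 8000)
#' duration(tone)
#' @export
audio_segment <- function(samples, sample_rate, start_time = 0) {
  abort_if(!is.numeric(samples) || length(samples) < 1L,
           "`samples` must be a non-empty numeric vector",
           class = "airleakr_argument_error")
  abort_if(any(!is.finite(samples)), "`samples` must all be finite",
           class = "airleakr_argument_error")
  check_number(sample_rate, "sample_rate", positive = TRUE)
  check_number(start_time, "start_time")
  structure(
    list(samples = as.double(samples), sample_rate = as.double(sample_rate),
         start_time = as.double(start_time)),
    class = "audio_segment"
  )
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment: %d samples @ %g Hz, %.3f s, peak %.3g>\n",
              length(x$samples), x$sample_rate, duration(x),
              max(abs(x$samples))))
  invisible(x)
}

#' Duration of an audio segment in seconds
#' @param segment An [audio_segment()].
#' @return Length of the segment in seconds.
#' @export
duration <- function(segment) {
  stopifnot(inherits(segment, "audio_segment"))
  length(segment$samples) / segment$sample_rate
}

#' @export
as_tibble.audio_segment <- function(x, ...) {
  tibble(
    time_s = x$start_time + (seq_along(x$samples) - 1) / x$sample_rate,
    amplitude = x$samples
  )
}

#' Extract a time window from an audio segment
#'
#' @param segment An [audio_segment()].
#' @param t0,t1 Window limits in seconds (same clock as `start_time`).
#' @return An [audio_segment()] whose `start_time` is the time of its first
#'   retained sample.
#' @export
crop <- function(segment, t0, t1) {
  stopifnot(inherits(segment, "audio_segment"))
  check_number(t0, "t0"); check_number(t1, "t1")
  abort_if(t1 <= t0, "`t1` must be greater than `t0`",
           class = "airleakr_argument_error")
  t <- segment$start_time + (seq_along(segment$samples) - 1) / segment$sample_rate
  keep <- which(t >= t0 & t < t1)
  abort_if(length(keep) == 0L, "window [", t0, ", ", t1, ") contains no samples",
           class = "airleakr_argument_error")
  audio_segment(segment$samples[keep], segment$sample_rate, start_time = t[keep[1]])
}

# WAV (RIFF) I/O --------------------------------------------------------------
# No audio package is part of the dependency stack, so the canonical RIFF/WAVE
# layout (PCM16, PCM24, IEEE float32; mono) is parsed and written directly.

wav_u32 <- function(raw4) sum(as.integer(raw4) * c(1, 256, 65536, 16777216))
wav_u16 <- function(raw2) sum(as.integer(raw2) * c(1, 256))

#' Read a mono WAV file
#'
#' Accepts PCM 16-bit, PCM 24-bit and IEEE float 32-bit RIFF/WAVE files.
#' Integer samples are normalized by full scale to the −1..+1 range.
#'
#' @param path Path to a WAV file.
#' @param average_channels If `TRUE`, a multi-channel file is reduced to mono
#'   by averaging channels; otherwise multi-channel input is an error.
#' @return An [audio_segment()] with `start_time = 0`.
#' @export
read_wav <- function(path, average_channels = FALSE) {
  abort_if(!file.exists(path), "file not found: ", path, class = "airleakr_io_error")
  raw <- readBin(path, "raw", n = file.info(path)$size)
  abort_if(length(raw) < 44 || rawToChar(raw[1:4]) != "RIFF" ||
             rawToChar(raw[9:12]) != "WAVE",
           "not a RIFF/WAVE file: ", path, class = "airleakr_format_error")
  pos <- 13L
  fmt <- NULL
  data_raw <- NULL
  while (pos + 8L <= length(raw)) {
    id <- rawToChar(raw[pos:(pos + 3L)])
    size <- wav_u32(raw[(pos + 4L):(pos + 7L)])
    body <- raw[(pos + 8L):min(pos + 7L + size, length(raw))]
    if (id == "fmt ") {
      fmt <- list(
        audio_format = wav_u16(body[1:2]),
        n_channels   = wav_u16(body[3:4]),
        sample_rate  = wav_u32(body[5:8]),
        bits         = wav_u16(body[15:16])
      )
    } else if (id == "data") {
      data_raw <- body
    }
    pos <- pos + 8L + size + (size %% 2L)  # chunks are word-aligned
  }
  abort_if(is.null(fmt) || is.null(data_raw), "missing fmt/data chunk in ", path,
           class = "airleakr_format_error")
  x <- switch(
    paste(fmt$audio_format, fmt$bits),
    "1 16" = readBin(data_raw, "integer", n = length(data_raw) / 2L, size = 2L,
                     signed = TRUE, endian = "little") / 32768,
    "1 24" = {
      m <- matrix(as.integer(data_raw), nrow = 3L)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      v[v >= 8388608] <- v[v >= 8388608] - 16777216
      v / 8388608
    },
    "3 32" = readBin(data_raw, "double", n = length(data_raw) / 4L, size = 4L,
                     endian = "little"),
    abort_if(TRUE, "unsupported WAV encoding (format ", fmt$audio_format,
             ", ", fmt$bits, " bit); expected PCM16, PCM24 or float32",
             class = "airleakr_format_error")
  )
  if (fmt$n_channels > 1L) {
    abort_if(!average_channels,
             "file has ", fmt$n_channels,
             " channels; mono required (set average_channels = TRUE to average)",
             class = "airleakr_format_error")
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  audio_segment(x, fmt$sample_rate, start_time = 0)
}

#' Write a mono WAV file
#'
#' @param segment An [audio_segment()] with samples in −1..+1 (unless `clip`).
#' @param path Output path.
#' @param bit_depth `"pcm16"` (default) or `"float32"`.
#' @param clip If `TRUE`, out-of-range samples are clipped to ±1 instead of
#'   raising an error.
#' @return `path`, invisibly.
#' @export
write_wav <- function(segment, path, bit_depth = c("pcm16", "float32"),
                      clip = FALSE) {
  stopifnot(inherits(segment, "audio_segment"))
  bit_depth <- match.arg(bit_depth)
  x <- segment$samples
  if (any(abs(x) > 1)) {
    abort_if(!clip, "samples exceed full scale (max |x| = ",
             format(max(abs(x))), "); set clip = TRUE to clip",
             class = "airleakr_argument_error")
    x <- pmin(1, pmax(-1, x))
  }
  rate <- as.integer(round(segment$sample_rate))
  if (bit_depth == "pcm16") {
    fmt_code <- 1L; bits <- 16L
    payload <- writeBin(as.integer(pmin(32767, round(x * 32768))), raw(),
                        size = 2L, endian = "little")
  } else {
    fmt_code <- 3L; bits <- 32L
    payload <- writeBin(x, raw(), size = 4L, endian = "little")
  }
  block_align <- bits %/% 8L
  con <- tryCatch(file(path, "wb"), error = function(e)
    abort_if(TRUE, "cannot open for writing: ", path, class = "airleakr_io_error"))
  on.exit(close(con))
  wr32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wr16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  writeChar("RIFF", con, eos = NULL); wr32(36L + length(payload))
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wr32(16L)
  wr16(fmt_code); wr16(1L); wr32(rate); wr32(rate * block_align)
  wr16(block_align); wr16(bits)
  writeChar("data", con, eos = NULL); wr32(length(payload))
  writeBin(payload, con)
  invisible(path)
}

#' Resample an audio segment by band-limited interpolation
#'
#' Fourier-domain resampling: the spectrum is truncated (downsampling) or
#' zero-padded (upsampling) so that tone frequencies below both Nyquist limits
#' are preserved within one FFT bin and total duration within one sample
#' period.
#'
#' @param segment An [audio_segment()].
#' @param target_rate New sampling rate in Hz (> 0).
#' @return An [audio_segment()] at `target_rate`.
#' @export
resample_audio <- function(segment, target_rate) {
  stopifnot(inherits(segment, "audio_segment"))
  check_number(target_rate, "target_rate", positive = TRUE)
  n_in <- length(segment$samples)
  if (isTRUE(all.equal(target_rate, segment$sample_rate))) {
    return(audio_segment(segment$samples, target_rate, segment$start_time))
  }
  n_out <- max(1L, as.integer(round(n_in * target_rate / segment$sample_rate)))
  X <- fft(segment$samples)
  Y <- complex(n_out)
  k <- min(n_in, n_out)
  n_keep <- (k - 1L) %/% 2L                  # positive-frequency bins kept
  Y[1] <- X[1]
  if (n_keep > 0) {
    Y[2:(n_keep + 1L)] <- X[2:(n_keep + 1L)]
    Y[(n_out - n_keep + 1L):n_out] <- X[(n_in - n_keep + 1L):n_in]
  }
  # content at exactly the boundary bin of the shorter grid is dropped;
  # band-limited inputs (anything below both Nyquist limits) are unaffected
  y <- Re(fft(Y, inverse = TRUE)) / n_in
  audio_segment(y, target_rate, segment$start_time)
}
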