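# Frequency-band detection, harmonic-series identification, and band-power
# regression. Air-leak sound spectra show narrow bands at integer multiples
# of a fundamental set by the oscillating pleural tissue; ventilator noise
# adds non-harmonic distractor bands that must be excluded.

#' Detect spectral frequency bands
#'
#' Finds local maxima of a power spectrum above a threshold within a
#' frequency range, merges peaks closer than `min_separation_hz` (keeping the
#' stronger), and labels the survivors `fb1`, `fb2`, ... in ascending
#' frequency. Band centers are the power-weighted centroids of each peak's
#' −3 dB neighborhood; peak powers are refined by parabolic interpolation of
#' the log-spectrum.
#'
#' @param spectrum A [power_spectrum()].
#' @param threshold_db Detection threshold in dB re full scale (−80 for the
#'   small-animal regime, −60 for the large-animal regime).
#' @param min_separation_hz Minimum spacing between band centers (default 200).
#' @param fmin,fmax Frequency search range in Hz.
#' @return A `frequency_bands` tibble with columns `label`, `center_hz`,
#'   `peak_power_db`, `bandwidth_hz`; zero rows when nothing exceeds the
#'   threshold.
#' @export
detect_bands <- function(spectrum, threshold_db = -80, min_separation_hz = 200,
                         fmin = 0, fmax = 10000) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  abort_if(nrow(spectrum) == 0, "empty spectrum", class = "airleakr_argument_error")
  abort_if(fmin >= fmax, "`fmin` must be below `fmax`", class = "airleakr_argument_error")
  f <- spectrum$frequency_hz
  p <- spectrum$power_db
  n <- length(p)
  in_range <- f >= fmin & f <= fmax
  # strict local maxima above threshold
  is_peak <- c(FALSE, p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n], FALSE) &
    p > threshold_db & in_range
  idx <- which(is_peak)
  empty <- tibble(label = character(), center_hz = double(),
                  peak_power_db = double(), bandwidth_hz = double())
  class(empty) <- c("frequency_bands", class(empty))
  if (length(idx) == 0) return(empty)
  # merge within min_separation: accept strongest first
  idx <- idx[order(p[idx], decreasing = TRUE)]
  kept <- integer()
  for (i in idx) {
    if (all(abs(f[i] - f[kept]) >= min_separation_hz)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  band_at <- function(i) {
    # -3 dB neighborhood around the local maximum
    lo <- i; while (lo > 1 && p[lo - 1] >= p[i] - 3 && p[lo - 1] <= p[lo]) lo <- lo - 1
    hi <- i; while (hi < n && p[hi + 1] >= p[i] - 3 && p[hi + 1] <= p[hi]) hi <- hi + 1
    w <- 10^(p[lo:hi] / 10)
    center <- sum(f[lo:hi] * w) / sum(w)
    # parabolic refinement of the peak level (counters Hann scalloping loss)
    peak_db <- p[i]
    if (i > 1 && i < n) {
      denom <- p[i - 1] - 2 * p[i] + p[i + 1]
      if (denom < 0) {
        delta <- 0.5 * (p[i - 1] - p[i + 1]) / denom
        peak_db <- p[i] - 0.25 * (p[i - 1] - p[i + 1]) * delta
      }
    }
    c(center, peak_db, f[hi] - f[lo])
  }
  m <- vapply(kept, band_at, numeric(3))
  out <- tibble(
    label = paste0("fb", seq_along(kept)),
    center_hz = m[1, ],
    peak_power_db = m[2, ],
    bandwidth_hz = m[3, ]
  )
  class(out) <- c("frequency_bands", class(out))
  out
}

#' Harmonic number of a frequency relative to a fundamental
#'
#' Returns `k = round(frequency / fundamental)` when the ratio is within
#' `tolerance` of that integer and `k >= 1`; otherwise `NA`. The default
#' tolerance 0.25 is the smallest that accepts the observed leak-band ratios
#' (e.g. 8845/1223 = 7.23).
#'
#' @param frequency Band frequency in Hz; vectorized.
#' @param fundamental Fundamental frequency in Hz (> 0).
#' @param tolerance Maximum absolute deviation of the ratio from an integer.
#' @return Integer harmonic number(s), `NA` where no integer fits.
#' @examples
#' harmonic_number(8845, 1223)  # 7
#' harmonic_number(2731, 665)   # 4
#' @export
harmonic_number <- function(frequency, fundamental, tolerance = 0.25) {
  check_number(fundamental, "fundamental", positive = TRUE)
  check_number(tolerance, "tolerance")
  ratio <- frequency / fundamental
  k <- round(ratio)
  k[abs(ratio - k) > tolerance | k < 1] <- NA_integer_
  as.integer(k)
}

#' Identify the harmonic series among detected bands
#'
#' Chooses as fundamental the band whose integer-multiple structure explains
#' the most bands (ties broken toward the lowest frequency); bands that fit
#' no integer multiple of the winner are reported as excluded (ventilator or
#' other non-harmonic noise). Harmonic numbers may skip integers.
#'
#' @param bands A `frequency_bands` tibble from [detect_bands()].
#' @param tolerance Ratio tolerance passed to [harmonic_number()].
#' @param min_members Minimum number of bands (fundamental included) the
#'   winning series must explain.
#' @return A `harmonic_series` object: `fundamental_hz`, `members` (tibble
#'   `label`, `center_hz`, `peak_power_db`, `harmonic_number`), `excluded`
#'   (same columns minus the harmonic number), `tolerance`.
#' @export
find_harmonic_series <- function(bands, tolerance = 0.25, min_members = 3) {
  stopifnot(inherits(bands, "frequency_bands") || is.data.frame(bands))
  abort_if(nrow(bands) < min_members,
           "need at least ", min_members, " bands, got ", nrow(bands),
           class = "airleakr_argument_error")
  bands <- bands[order(bands$center_hz), ]   # ties resolve toward lowest frequency
  score <- function(f0) {
    k <- harmonic_number(bands$center_hz, f0, tolerance)
    # duplicate harmonic numbers: keep the best-fitting band
    resid <- abs(bands$center_hz / f0 - k)
    keep <- !is.na(k)
    for (kk in unique(k[keep])) {
      ties <- which(!is.na(k) & k == kk)
      if (length(ties) > 1) {
        drop <- ties[-which.min(resid[ties])]
        k[drop] <- NA_integer_
      }
    }
    k
  }
  assignments <- lapply(bands$center_hz, score)
  counts <- vapply(assignments, function(k) sum(!is.na(k)), integer(1))
  best_n <- max(counts)
  if (best_n < min_members) {
    cand <- which.max(counts)
    abort_if(TRUE, "no fundamental explains >= ", min_members,
             " bands; best candidate ", round(bands$center_hz[cand], 1),
             " Hz explains ", best_n,
             class = "airleakr_analysis_error")
  }
  winner <- which(counts == best_n)[1]   # candidates are in ascending frequency
  k <- assignments[[winner]]
  members <- bands[!is.na(k), c("label", "center_hz", "peak_power_db")]
  members$harmonic_number <- k[!is.na(k)]
  members <- members[order(members$harmonic_number), ]
  structure(
    list(
      fundamental_hz = bands$center_hz[winner],
      members = as_tibble(members),
      excluded = as_tibble(bands[is.na(k), c("label", "center_hz", "peak_power_db")]),
      tolerance = tolerance
    ),
    class = "harmonic_series"
  )
}

#' @export
print.harmonic_series <- function(x, ...) {
  cat(sprintf("<harmonic_series: f0 = %.1f Hz, harmonics {%s}, %d excluded>\n",
              x$fundamental_hz,
              paste(x$members$harmonic_number, collapse = ","),
              nrow(x$excluded)))
  invisible(x)
}

#' Linear regression of band power on band frequency
#'
#' Ordinary least squares of peak band power (dB) on band center frequency
#' (Hz), the inverse intensity-frequency relationship characteristic of leak
#' harmonics. Returns a `band_regression` object with [tidy()] and
#' [glance()] methods.
#'
#' @param bands A `frequency_bands` tibble (>= 3 rows) from [detect_bands()],
#'   or any data frame with `center_hz` and `peak_power_db` columns.
#' @return A `band_regression` object with fields `slope` (dB/Hz),
#'   `intercept` (dB), `r_squared`, `p_value`, `n` and the underlying `fit`.
#' @export
band_power_regression <- function(bands) {
  abort_if(!all(c("center_hz", "peak_power_db") %in% names(bands)),
           "`bands` needs `center_hz` and `peak_power_db` columns",
           class = "airleakr_argument_error")
  abort_if(nrow(bands) < 3, "need >= 3 bands for regression, got ", nrow(bands),
           class = "airleakr_argument_error")
  abort_if(var(bands$center_hz) == 0, "band frequencies are identical",
           class = "airleakr_argument_error")
  fit <- lm(peak_power_db ~ center_hz, data = bands)
  # exact synthetic lines are legitimate input; silence the perfect-fit advisory
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  ss_tot <- sum((bands$peak_power_db - mean(bands$peak_power_db))^2)
  r2 <- if (ss_tot == 0) 0 else sm$r.squared       # flat data: no variance explained
  p <- if (ss_tot == 0) 1 else sm$coefficients["center_hz", "Pr(>|t|)"]
  structure(
    list(slope = unname(coef(fit)["center_hz"]),
         intercept = unname(coef(fit)["(Intercept)"]),
         r_squared = r2, p_value = p, n = nrow(bands), fit = fit),
    class = "band_regression"
  )
}

#' @export
print.band_regression <- function(x, ...) {
  cat(sprintf("<band_regression: Y = %.5gX %+.4g (dB vs Hz), R2 = %.3f, p = %.3g, n = %d>\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' @rdname band_power_regression
#' @param x A `band_regression` object.
#' @param ... Unused.
#' @export
tidy.band_regression <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p.value = unname(sm[, "Pr(>|t|)"])
  )
}

#' @rdname band_power_regression
#' @export
glance.band_regression <- function(x, ...) {
  tibble(r.squared = x$r_squared, p.value = x$p_value, n = x$n)
}
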