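# Seeded synthetic acoustic scenes with ground truth: ventilator pressure
# waveform, pressure-modulated harmonic leak source, sub-400 Hz heart sounds,
# stationary equipment tones, Gaussian ambient noise, and distance-attenuated
# microphone-grid recordings. The generator emulates the two study regimes
# (small-animal: 70 bpm, ~16 cmH2O peaks, fundamental 1223 Hz with harmonics
# {1,2,3,4,5,7} plus an 890 Hz ventilator tone; large-animal: 15 bpm, PEEP 5
# cmH2O, fundamental 665 Hz with harmonics 1-4).

#' Construct a synthetic scene configuration
#'
#' @param sample_rate Audio sampling rate in Hz.
#' @param duration_s Scene duration in seconds.
#' @param vent Ventilator waveform: list with `bpm`, `pip` (peak inspiratory
#'   pressure, cmH2O), `peep` (end-expiratory pressure, cmH2O),
#'   `rise_fraction` and `plateau_fraction` (fractions of the breath period).
#' @param leak Leak source: list with `fundamental_hz`, `harmonic_numbers`
#'   (strictly increasing positive integers), `power_slope_db_per_hz` and
#'   `power_intercept_db` (per-band peak power law, dB re full scale),
#'   `pressure_exponent` (loudness vs driving-pressure exponent, default 1),
#'   `strength` (linear gain, the severity dial). `NULL` for no leak.
#' @param extra_tones Data frame with columns `hz`, `level_db` of stationary
#'   equipment tones (e.g. ventilator hum), or `NULL`.
#' @param heart Heart-sound component: list with `bpm`, `s1_hz`, `s2_hz`
#'   (burst center frequencies, <= 200 Hz), `burst_duration_s`, `level_db`
#'   (peak amplitude in dB re full scale). `NULL` for no heart sound.
#' @param ambient_level_db RMS level of Gaussian ambient noise in dB re full
#'   scale (`-Inf` for none).
#' @param pressure_rate_hz Sampling rate of the generated pressure trace.
#' @param seed Integer seed; identical config + seed gives identical scenes.
#' @return A `scene_config` list.
#' @seealso [rat_scene_config()], [swine_scene_config()]
#' @export
scene_config <- function(sample_rate = 22050, duration_s = 4,
                         vent = list(bpm = 70, pip = 16.2, peep = 2,
                                     rise_fraction = 0.35, plateau_fraction = 0.3),
                         leak = list(fundamental_hz = 1223,
                                     harmonic_numbers = c(1, 2, 3, 4, 5, 7),
                                     power_slope_db_per_hz = -0.00231,
                                     power_intercept_db = -49.1,
                                     pressure_exponent = 1, strength = 1),
                         extra_tones = NULL, heart = NULL,
                         ambient_level_db = -70, pressure_rate_hz = 200,
                         seed = 1L) {
  check_number(sample_rate, "sample_rate", positive = TRUE)
  check_number(duration_s, "duration_s", positive = TRUE)
  abort_if(vent$pip <= vent$peep, "`vent$pip` must exceed `vent$peep`",
           class = "airleakr_config_error")
  abort_if(vent$rise_fraction < 0 || vent$plateau_fraction < 0 ||
             vent$rise_fraction + vent$plateau_fraction >= 1,
           "rise_fraction + plateau_fraction must be in [0, 1)",
           class = "airleakr_config_error")
  if (!is.null(leak)) {
    k <- leak$harmonic_numbers
    abort_if(any(k < 1) || any(k != round(k)) || any(diff(k) <= 0),
             "`leak$harmonic_numbers` must be strictly increasing positive integers",
             class = "airleakr_config_error")
    abort_if(max(k) * leak$fundamental_hz >= sample_rate / 2,
             "harmonic ", max(k), " x ", leak$fundamental_hz,
             " Hz is at or above Nyquist", class = "airleakr_config_error")
    leak$pressure_exponent <- leak$pressure_exponent %||% 1
    leak$strength <- leak$strength %||% 1
  }
  if (!is.null(heart)) {
    abort_if(max(heart$s1_hz, heart$s2_hz) > 200,
             "heart burst centers must be <= 200 Hz", class = "airleakr_config_error")
    sigma_f <- 3 / (pi * heart$burst_duration_s)  # spectral sd of the burst
    abort_if(max(heart$s1_hz, heart$s2_hz) + 6 * sigma_f >= 400,
             "heart config violates the < 400 Hz spectral bound",
             class = "airleakr_config_error")
  }
  if (!is.null(extra_tones)) {
    abort_if(any(extra_tones$hz >= sample_rate / 2),
             "extra tone at or above Nyquist", class = "airleakr_config_error")
  }
  structure(
    list(sample_rate = sample_rate, duration_s = duration_s, vent = vent,
         leak = leak, extra_tones = extra_tones, heart = heart,
         ambient_level_db = ambient_level_db,
         pressure_rate_hz = pressure_rate_hz, seed = as.integer(seed)),
    class = "scene_config"
  )
}

#' Small-animal (rat-regime) scene preset
#'
#' 70 breaths/min with 16.2 cmH2O peaks; leak fundamental 1223 Hz with
#' harmonics \{1,2,3,4,5,7\} (harmonic 6 deliberately absent, mirroring the
#' observed series) on the band-power law Y = -0.00231 X - 49.1 dB, plus a
#' stationary 890 Hz ventilator tone louder than the fundamental so that
#' harmonic-series exclusion is exercised.
#'
#' @param duration_s Scene length in seconds.
#' @param leak_strength Linear leak gain (severity dial).
#' @param ambient_level_db Ambient noise RMS in dB re full scale.
#' @param seed Integer seed.
#' @param ... Overrides passed to [scene_config()].
#' @return A `scene_config`.
#' @export
rat_scene_config <- function(duration_s = 4, leak_strength = 1,
                             ambient_level_db = -70, seed = 1L, ...) {
  scene_config(
    sample_rate = 22050, duration_s = duration_s,
    vent = list(bpm = 70, pip = 16.2, peep = 2,
                rise_fraction = 0.35, plateau_fraction = 0.3),
    leak = list(fundamental_hz = 1223, harmonic_numbers = c(1, 2, 3, 4, 5, 7),
                power_slope_db_per_hz = -0.00231, power_intercept_db = -49.1,
                pressure_exponent = 1, strength = leak_strength),
    extra_tones = data.frame(hz = 890, level_db = -48),
    heart = NULL, ambient_level_db = ambient_level_db, seed = seed, ...
  )
}

#' Large-animal (swine-regime) scene preset
#'
#' 15 breaths/min, PEEP 5 cmH2O, PIP 20 cmH2O; leak fundamental 665 Hz with
#' harmonics 1-4 on the band-power law Y = -0.00792 X - 34.8 dB.
#'
#' @inheritParams rat_scene_config
#' @return A `scene_config`.
#' @export
swine_scene_config <- function(duration_s = 8, leak_strength = 1,
                               ambient_level_db = -70, seed = 1L, ...) {
  scene_config(
    sample_rate = 16000, duration_s = duration_s,
    vent = list(bpm = 15, pip = 20, peep = 5,
                rise_fraction = 0.3, plateau_fraction = 0.3),
    leak = list(fundamental_hz = 665, harmonic_numbers = 1:4,
                power_slope_db_per_hz = -0.00792, power_intercept_db = -34.8,
                pressure_exponent = 1, strength = leak_strength),
    extra_tones = NULL, heart = NULL, ambient_level_db = ambient_level_db,
    seed = seed, ...
  )
}

#' Heart-sound demonstration preset
#'
#' Heart-only scene (no ventilator-driven leak sound, no ambient noise):
#' 60 bpm S1/S2 Gaussian tone bursts with all spectral content below 400 Hz.
#'
#' @inheritParams rat_scene_config
#' @return A `scene_config`.
#' @export
heart_scene_config <- function(duration_s = 10, seed = 1L, ...) {
  scene_config(
    sample_rate = 4000, duration_s = duration_s,
    vent = list(bpm = 60, pip = 10, peep = 0,
                rise_fraction = 0.35, plateau_fraction = 0.3),
    leak = NULL, extra_tones = NULL,
    heart = list(bpm = 60, s1_hz = 120, s2_hz = 90,
                 burst_duration_s = 0.06, level_db = -30),
    ambient_level_db = -Inf, seed = seed, ...
  )
}

#' Generate the ventilator pressure waveform
#'
#' Periodic positive-pressure waveform with period 60/bpm: linear rise from
#' PEEP to PIP over `rise_fraction` of the breath, plateau hold over
#' `plateau_fraction`, then exponential decay back to PEEP.
#'
#' @param config A [scene_config()].
#' @return A [pressure_trace()] sampled at `config$pressure_rate_hz`.
#' @export
gen_pressure <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  v <- config$vent
  t <- seq(0, config$duration_s, by = 1 / config$pressure_rate_hz)
  period <- 60 / v$bpm
  phase <- (t %% period) / period
  rise_end <- v$rise_fraction
  plat_end <- v$rise_fraction + v$plateau_fraction
  tau <- (1 - plat_end) / 5   # decay reaches PEEP within the breath
  p <- ifelse(
    phase < rise_end,
    v$peep + (v$pip - v$peep) * phase / max(rise_end, .Machine$double.eps),
    ifelse(phase < plat_end, v$pip,
           v$peep + (v$pip - v$peep) * exp(-(phase - plat_end) / max(tau, 1e-9)))
  )
  pressure_trace(t, p, ambient_cmh2o = 0)
}

#' Generate the harmonic leak sound
#'
#' Sum over the configured harmonic numbers k of `a_k sin(2 pi k f0 t +
#' phi_k)` with each `a_k` set so its peak band power in dB equals
#' `power_slope_db_per_hz * (k f0) + power_intercept_db`, amplitude-modulated
#' by the normalized driving pressure `max(0, P(t) - ambient)^exponent` and
#' scaled by `strength`. Phases are drawn from the config seed.
#'
#' @param config A [scene_config()] with a non-`NULL` `leak`.
#' @param pressure Optional [pressure_trace()]; defaults to
#'   [gen_pressure()] of the config.
#' @return An [audio_segment()].
#' @export
gen_leak_sound <- function(config, pressure = NULL) {
  stopifnot(inherits(config, "scene_config"))
  abort_if(is.null(config$leak), "config has no leak component",
           class = "airleakr_config_error")
  pressure <- pressure %||% gen_pressure(config)
  lk <- config$leak
  t <- seq(0, config$duration_s, by = 1 / config$sample_rate)
  t <- t[-length(t)]
  p <- approx(pressure$time_s, pressure$pressure_cmh2o, xout = t, rule = 2)$y
  drive <- pmax(0, p - attr(pressure, "ambient_cmh2o"))^lk$pressure_exponent
  if (max(drive) == 0) {
    return(audio_segment(numeric(length(t)) + 0 * t, config$sample_rate))
  }
  env <- lk$strength * drive / max(drive)
  k <- lk$harmonic_numbers
  amps <- 10^((lk$power_slope_db_per_hz * k * lk$fundamental_hz +
                 lk$power_intercept_db) / 20)
  phases <- withr::with_seed(config$seed, runif(length(k), 0, 2 * pi))
  y <- numeric(length(t))
  for (j in seq_along(k)) {
    y <- y + amps[j] * sin(2 * pi * k[j] * lk$fundamental_hz * t + phases[j])
  }
  audio_segment(env * y, config$sample_rate)
}

#' Generate heart sounds
#'
#' Per beat, two Gaussian-windowed tone bursts (S1 and S2, S2 following S1 by
#' 0.3 s at 0.8x amplitude) with configured center frequencies; all spectral
#' power is confined below 400 Hz by construction (burst bandwidth is checked
#' at configuration time).
#'
#' @param config A [scene_config()] with a non-`NULL` `heart`.
#' @return An [audio_segment()].
#' @export
gen_heart_sound <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  abort_if(is.null(config$heart), "config has no heart component",
           class = "airleakr_config_error")
  h <- config$heart
  if (!is.finite(h$level_db)) {
    n <- as.integer(config$duration_s * config$sample_rate)
    return(audio_segment(numeric(n), config$sample_rate))
  }
  t <- seq(0, config$duration_s, by = 1 / config$sample_rate)
  t <- t[-length(t)]
  amp <- 10^(h$level_db / 20)
  sigma <- h$burst_duration_s / 6
  y <- numeric(length(t))
  burst <- function(center_t, f, a) {
    a * exp(-(t - center_t)^2 / (2 * sigma^2)) * sin(2 * pi * f * (t - center_t))
  }
  beat_times <- seq(0.2, config$duration_s, by = 60 / h$bpm)
  for (tb in beat_times) {
    y <- y + burst(tb, h$s1_hz, amp)
    y <- y + burst(tb + 0.3, h$s2_hz, 0.8 * amp)
  }
  audio_segment(y, config$sample_rate)
}

#' Generate a complete acoustic scene with ground truth
#'
#' Mixes the leak sound, heart sounds, stationary equipment tones and seeded
#' Gaussian ambient noise, and returns the mixture together with the
#' generator truth needed to score every estimator.
#'
#' @param config A [scene_config()].
#' @return A list with `audio` (an [audio_segment()]) and `truth` (list:
#'   `pressure`, `fundamental_hz`, `harmonic_numbers`, `component_rms`,
#'   `seed`, `config`).
#' @export
gen_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  pressure <- gen_pressure(config)
  n <- length(seq(0, config$duration_s, by = 1 / config$sample_rate)) - 1L
  t <- (seq_len(n) - 1) / config$sample_rate
  y <- numeric(n)
  rms <- function(x) sqrt(mean(x^2))
  comp_rms <- c(leak = 0, heart = 0, tones = 0, ambient = 0)
  if (!is.null(config$leak)) {
    leak <- gen_leak_sound(config, pressure)$samples
    y <- y + leak
    comp_rms["leak"] <- rms(leak)
  }
  if (!is.null(config$heart)) {
    heart <- gen_heart_sound(config)$samples
    y <- y + heart
    comp_rms["heart"] <- rms(heart)
  }
  if (!is.null(config$extra_tones)) {
    tone_phases <- withr::with_seed(config$seed + 1L,
                                    runif(nrow(config$extra_tones), 0, 2 * pi))
    tones <- numeric(n)
    for (i in seq_len(nrow(config$extra_tones))) {
      tones <- tones + 10^(config$extra_tones$level_db[i] / 20) *
        sin(2 * pi * config$extra_tones$hz[i] * t + tone_phases[i])
    }
    y <- y + tones
    comp_rms["tones"] <- rms(tones)
  }
  if (is.finite(config$ambient_level_db)) {
    noise <- withr::with_seed(config$seed + 2L,
                              rnorm(n, sd = 10^(config$ambient_level_db / 20)))
    y <- y + noise
    comp_rms["ambient"] <- rms(noise)
  }
  list(
    audio = audio_segment(y, config$sample_rate),
    truth = list(
      pressure = pressure,
      fundamental_hz = if (is.null(config$leak)) NA_real_ else config$leak$fundamental_hz,
      harmonic_numbers = if (is.null(config$leak)) integer() else
        as.integer(config$leak$harmonic_numbers),
      component_rms = comp_rms,
      seed = config$seed,
      config = config
    )
  )
}

#' Generate microphone-grid recordings with a known leak site
#'
#' Emulates the grid-localization protocol: one recording per cell with the
#' leak component attenuated as `standoff / r` (spherical spreading with a
#' near-field floor at the microphone standoff), where `r` is the Euclidean
#' distance from the leak site to the microphone above the cell center, plus
#' independent seeded Gaussian ambient noise per cell at the given SNR
#' relative to the loudest cell.
#'
#' @param config A [scene_config()] with a leak component.
#' @param n_rows,n_cols Grid dimensions.
#' @param step_cm Grid step in cm (default 1).
#' @param leak_cell Integer `c(row, col)` of the leak site, or `NULL` for a
#'   no-leak (ambient only) grid.
#' @param standoff_cm Microphone standoff above the surface in cm (default 1).
#' @param snr_db Signal-to-noise ratio in dB at the loudest cell.
#' @return A list with `recordings` (tibble `row`, `col`, `audio`) and
#'   `truth` (list incl. `leak_cell`, `position_cm` of the source).
#' @export
gen_grid_recordings <- function(config, n_rows = 5, n_cols = 5, step_cm = 1,
                                leak_cell = c(3, 3), standoff_cm = 1,
                                snr_db = 10) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(leak_cell)) {
    abort_if(length(leak_cell) != 2 ||
               leak_cell[1] < 1 || leak_cell[1] > n_rows ||
               leak_cell[2] < 1 || leak_cell[2] > n_cols,
             "`leak_cell` (", paste(leak_cell, collapse = ","),
             ") outside the ", n_rows, "x", n_cols, " grid",
             class = "airleakr_argument_error")
  }
  leak <- if (is.null(leak_cell)) NULL else gen_leak_sound(config)$samples
  n <- as.integer(config$duration_s * config$sample_rate)
  noise_sd <- if (is.null(leak_cell)) {
    10^(config$ambient_level_db / 20)
  } else {
    sqrt(mean(leak^2)) / 10^(snr_db / 20)
  }
  cells <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols))
  audio <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    gain <- if (is.null(leak_cell)) 0 else {
      d_surf <- step_cm * sqrt((cells$row[i] - leak_cell[1])^2 +
                                 (cells$col[i] - leak_cell[2])^2)
      standoff_cm / sqrt(d_surf^2 + standoff_cm^2)
    }
    noise <- withr::with_seed(config$seed + 100L + i, rnorm(n, sd = noise_sd))
    x <- noise
    if (!is.null(leak_cell)) x <- x + gain * leak
    audio[[i]] <- audio_segment(x, config$sample_rate)
  }
  cells$audio <- audio
  list(
    recordings = cells,
    truth = list(
      leak_cell = leak_cell,
      position_cm = if (is.null(leak_cell)) NULL else
        c(x = (leak_cell[2] - 1) * step_cm, y = (leak_cell[1] - 1) * step_cm),
      standoff_cm = standoff_cm, snr_db = snr_db, step_cm = step_cm,
      seed = config$seed, config = config
    )
  )
}
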