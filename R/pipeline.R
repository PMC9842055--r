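# End-to-end orchestration: assessment of a recording + pressure trace,
# scene/grid simulation to files, grid localization from a manifest, and
# heart-sound removal. These functions are the programmatic interface; the
# thin command-line front-end in inst/cli/airleak only dispatches to them.

#' Analysis presets for the two study regimes
#'
#' The small-animal (`"rat"`) regime uses a −80 dB band threshold over
#' 0–10 kHz; the large-animal (`"swine"`) regime uses −60 dB over 0–5 kHz.
#' Both are dB re full scale and overridable.
#'
#' @param preset `"rat"` or `"swine"`.
#' @return List with `threshold_db`, `fmin`, `fmax`.
#' @export
analysis_preset <- function(preset = c("rat", "swine")) {
  preset <- match.arg(preset)
  switch(preset,
         rat = list(threshold_db = -80, fmin = 0, fmax = 10000),
         swine = list(threshold_db = -60, fmin = 0, fmax = 5000))
}

# averaged power spectrum over all inspiratory-plateau windows
plateau_spectrum <- function(segment, seg_breaths) {
  windows <- seg_breaths[seg_breaths$plateau_t1 - seg_breaths$plateau_t0 > 0, ]
  abort_if(nrow(windows) == 0, "no usable plateau window",
           class = "airleakr_analysis_error")
  rate <- segment$sample_rate
  n_min <- floor(min(windows$plateau_t1 - windows$plateau_t0) * rate)
  n_fft <- min(4096L, 2L^max(4L, floor(log2(n_min))))
  specs <- lapply(seq_len(nrow(windows)), function(i) {
    power_spectrum(segment, windows$plateau_t0[i], windows$plateau_t1[i],
                   n_fft = n_fft)
  })
  out <- specs[[1]]
  lin <- rowMeans(vapply(specs, function(s) 10^(s$power_db / 10),
                         numeric(nrow(out))))
  out$power_db <- 10 * log10(pmax(lin, 1e-300))
  attr(out, "source_window") <- c(min(windows$plateau_t0), max(windows$plateau_t1))
  out
}

#' Assess an air-leak recording
#'
#' Runs the full severity-assessment chain on a sound recording with its
#' synchronized airway-pressure trace: SPL series, breath segmentation,
#' pressure-loudness correlation, plateau power spectrum, band detection,
#' harmonic-series identification, band-power regression, phase slopes, and
#' severity grading. Baseline SPL defaults to the 10th percentile of the SPL
#' series (the quiet expiratory floor) when no explicit baseline is given.
#'
#' @param audio An [audio_segment()].
#' @param pressure A [pressure_trace()] synchronized with `audio` (t = 0).
#' @param preset `"rat"` or `"swine"` (see [analysis_preset()]).
#' @param calibration_offset dB offset mapping full scale to absolute SPL.
#' @param baseline_spl_dba Optional baseline loudness in dBA.
#' @param thresholds Severity cut-points from [severity_thresholds()].
#' @param volume_loss_ml_per_breath Optional ventilator-measured loss.
#' @param min_prominence Breath-detection prominence in cmH2O.
#' @return A `leak_assessment` list: `spl_summary`, `correlation`, `breaths`,
#'   `bands`, `harmonics`, `regression`, `severity`, `spectrum`, `provenance`.
#' @export
assess_recording <- function(audio, pressure, preset = c("rat", "swine"),
                             calibration_offset = 94, baseline_spl_dba = NULL,
                             thresholds = severity_thresholds(),
                             volume_loss_ml_per_breath = NA_real_,
                             min_prominence = 2) {
  preset <- match.arg(preset)
  ap <- analysis_preset(preset)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_if(TRUE, "stage '", name, "' failed: ", conditionMessage(e),
               class = "airleakr_pipeline_error")
    })
  }
  spl <- stage("spl", spl_series(audio, calibration_offset = calibration_offset))
  # a flat trace (no ventilation, or disconnected sensor) yields no breaths;
  # the assessment then falls back to whole-recording statistics
  breaths <- tryCatch(detect_breaths(pressure, min_prominence),
                      airleakr_analysis_error = function(e) {
                        out <- tibble(breath = integer(), t_start = double(),
                                      t_peak = double(), t_end = double(),
                                      peak_pressure = double(),
                                      plateau_t0 = double(), plateau_t1 = double())
                        class(out) <- c("breath_segmentation", class(out))
                        out
                      })
  correlation <- tryCatch(correlate_spl_pressure(spl, pressure),
                          airleakr_analysis_error = function(e) e,
                          airleakr_argument_error = function(e) e)
  spectrum <- if (nrow(breaths) > 0) {
    stage("plateau_spectrum", plateau_spectrum(audio, breaths))
  } else {
    stage("plateau_spectrum", power_spectrum(audio))
  }
  bands <- stage("bands", detect_bands(spectrum, threshold_db = ap$threshold_db,
                                       fmin = ap$fmin, fmax = ap$fmax))
  harmonics <- if (nrow(bands) >= 3) {
    tryCatch(find_harmonic_series(bands), airleakr_analysis_error = function(e) NULL)
  } else NULL
  regression <- if (nrow(bands) >= 3) stage("regression", band_power_regression(bands)) else NULL
  slopes <- if (nrow(breaths) > 0) {
    tryCatch(phase_slopes(spl, breaths), airleakr_analysis_error = function(e) NULL)
  } else NULL
  plateau_idx <- rep(FALSE, nrow(spl))
  for (i in seq_len(nrow(breaths))) {
    plateau_idx <- plateau_idx |
      (spl$time_s >= breaths$plateau_t0[i] & spl$time_s <= breaths$plateau_t1[i])
  }
  plateau_spl <- if (any(plateau_idx)) mean(spl$dba[plateau_idx]) else mean(spl$dba)
  baseline <- baseline_spl_dba %||% unname(quantile(spl$dba, 0.1))
  severity <- classify_severity(plateau_spl, baseline, thresholds,
                                volume_loss_ml_per_breath, slopes)
  structure(
    list(
      spl_summary = tibble(
        min_dba = min(spl$dba), max_dba = max(spl$dba), mean_dba = mean(spl$dba),
        plateau_dba = plateau_spl, baseline_dba = baseline
      ),
      spl = spl,
      correlation = if (inherits(correlation, "error")) NULL else correlation,
      breaths = breaths, bands = bands, harmonics = harmonics,
      regression = regression, phase_slopes = slopes, severity = severity,
      spectrum = spectrum,
      provenance = list(
        preset = preset, calibration_offset = calibration_offset,
        threshold_db = ap$threshold_db, band_range_hz = c(ap$fmin, ap$fmax),
        n_samples = length(audio$samples), sample_rate = audio$sample_rate,
        package_version = as.character(utils::packageVersion("airleakr"))
      )
    ),
    class = "leak_assessment"
  )
}

#' @export
print.leak_assessment <- function(x, ...) {
  cat("<leak_assessment>\n")
  cat(sprintf("  SPL: %.1f-%.1f dBA (plateau %.1f, baseline %.1f)\n",
              x$spl_summary$min_dba, x$spl_summary$max_dba,
              x$spl_summary$plateau_dba, x$spl_summary$baseline_dba))
  if (!is.null(x$correlation))
    cat(sprintf("  pressure-SPL correlation rho = %.3f\n", x$correlation$rho))
  cat(sprintf("  %d breaths, %d bands", nrow(x$breaths), nrow(x$bands)))
  if (!is.null(x$harmonics))
    cat(sprintf(", f0 = %.0f Hz (harmonics %s)", x$harmonics$fundamental_hz,
                paste(x$harmonics$members$harmonic_number, collapse = ",")))
  cat("\n")
  if (!is.null(x$regression))
    cat(sprintf("  band power: Y = %.5gX %+.4g, R2 = %.2f\n",
                x$regression$slope, x$regression$intercept, x$regression$r_squared))
  cat(sprintf("  severity: %s\n", as.character(x$severity$severity_class)))
  invisible(x)
}

#' Serialize a leak assessment to JSON
#'
#' Writes every numeric result of [assess_recording()] to a JSON report that
#' round-trips losslessly through [jsonlite::fromJSON()].
#'
#' @param assessment A `leak_assessment`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when `path` is given.
#' @export
assessment_to_json <- function(assessment, path = NULL) {
  stopifnot(inherits(assessment, "leak_assessment"))
  x <- list(
    spl_summary = as.list(assessment$spl_summary),
    correlation = if (is.null(assessment$correlation)) NULL else
      as.list(assessment$correlation),
    breaths = as.data.frame(assessment$breaths),
    bands = as.data.frame(assessment$bands),
    harmonics = if (is.null(assessment$harmonics)) NULL else list(
      fundamental_hz = assessment$harmonics$fundamental_hz,
      members = as.data.frame(assessment$harmonics$members),
      excluded = as.data.frame(assessment$harmonics$excluded)
    ),
    regression = if (is.null(assessment$regression)) NULL else
      assessment$regression[c("slope", "intercept", "r_squared", "p_value", "n")],
    severity = {
      s <- as.list(assessment$severity)
      s$severity_class <- as.character(s$severity_class)
      s
    },
    provenance = assessment$provenance
  )
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Simulate a scene to files
#'
#' Writes the scene WAV, the pressure CSV and a truth JSON for a
#' configuration — the file-level counterpart of [gen_scene()].
#'
#' @param config A [scene_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
simulate_scene <- function(config, out_dir) {
  stopifnot(inherits(config, "scene_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scene <- gen_scene(config)
  paths <- list(
    wav = file.path(out_dir, "scene.wav"),
    pressure = file.path(out_dir, "pressure.csv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_wav(scene$audio, paths$wav, bit_depth = "float32")
  write_pressure_csv(scene$truth$pressure, paths$pressure)
  truth <- scene$truth
  truth$pressure <- NULL
  truth$config <- unclass(truth$config)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA, null = "null"),
             paths$truth)
  invisible(paths)
}

#' Simulate grid recordings to files
#'
#' Writes one WAV per grid cell plus a `manifest.csv` (columns `row`, `col`,
#' `wav_path`) consumable by [localize_grid()], and a truth JSON.
#'
#' @param config A [scene_config()] with a leak component.
#' @param out_dir Output directory.
#' @inheritParams gen_grid_recordings
#' @return Invisibly, the manifest path.
#' @export
simulate_grid <- function(config, out_dir, n_rows = 5, n_cols = 5, step_cm = 1,
                          leak_cell = c(3, 3), standoff_cm = 1, snr_db = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- gen_grid_recordings(config, n_rows, n_cols, step_cm, leak_cell,
                              standoff_cm, snr_db)
  rec <- grid$recordings
  rec$wav_path <- sprintf("cell_r%02d_c%02d.wav", rec$row, rec$col)
  for (i in seq_len(nrow(rec))) {
    write_wav(rec$audio[[i]], file.path(out_dir, rec$wav_path[i]),
              bit_depth = "float32", clip = TRUE)
  }
  manifest <- file.path(out_dir, "manifest.csv")
  write.csv(rec[, c("row", "col", "wav_path")], manifest,
            row.names = FALSE, quote = FALSE)
  truth <- grid$truth
  truth$config <- NULL
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA, null = "null"),
             file.path(out_dir, "truth.json"))
  invisible(manifest)
}

#' Localize a leak from a grid manifest
#'
#' Reads the per-cell WAVs listed in a manifest CSV (`row`, `col`,
#' `wav_path`, paths relative to the manifest), builds and normalizes the
#' intensity matrix, and locates the leak. When the normalized intensity
#' spread (max − min) is below `no_leak_margin` the location is flagged as
#' "no leak detected" — a near-uniform matrix carries no spatial signal.
#'
#' @param manifest_csv Path to the manifest CSV.
#' @param step_cm Grid step in cm.
#' @param duration_s,calibration_offset Passed to [build_intensity_matrix()].
#' @param no_leak_margin Spread threshold for the no-leak flag (default 0.1).
#' @return A list: `matrix` (normalized `intensity_matrix`), `location`
#'   (`leak_location`), `no_leak` (logical), `spread`.
#' @export
localize_grid <- function(manifest_csv, step_cm = 1, duration_s = 5,
                          calibration_offset = 94, no_leak_margin = 0.1) {
  abort_if(!file.exists(manifest_csv), "file not found: ", manifest_csv,
           class = "airleakr_io_error")
  man <- read.csv(manifest_csv, stringsAsFactors = FALSE)
  abort_if(!all(c("row", "col", "wav_path") %in% names(man)),
           "manifest needs columns row, col, wav_path",
           class = "airleakr_format_error")
  base <- dirname(manifest_csv)
  man$audio <- lapply(man$wav_path, function(p) read_wav(file.path(base, p)))
  m <- build_intensity_matrix(as_tibble(man[, c("row", "col", "audio")]),
                              step_cm = step_cm, duration_s = duration_s,
                              calibration_offset = calibration_offset)
  m <- normalize_intensity(m)
  spread <- max(m$normalized) - min(m$normalized)
  list(matrix = m, location = locate_leak(m),
       no_leak = spread < no_leak_margin, spread = spread)
}

#' Write an intensity matrix as TSV
#'
#' Long-format TSV (`row`, `col`, `x_cm`, `y_cm`, `raw_dba`, `normalized`).
#'
#' @param matrix An `intensity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  utils::write.table(as_tibble(matrix), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Remove heart sounds from a recording file
#'
#' High-pass filters a WAV (default 500 Hz cutoff, zero-phase Butterworth)
#' and writes the result, returning a summary of the removed low-band power.
#'
#' @param wav_in,wav_out Input and output WAV paths.
#' @param cutoff_hz High-pass cutoff in Hz (default 500).
#' @param order Butterworth order (default 4).
#' @return Invisibly, a tibble with the sub-cutoff band power before and
#'   after filtering (dB re full scale) and the attenuation achieved.
#' @export
filter_heart <- function(wav_in, wav_out, cutoff_hz = 500, order = 4) {
  audio <- read_wav(wav_in)
  filtered <- highpass(audio, cutoff_hz, order)
  write_wav(filtered, wav_out, bit_depth = "float32", clip = TRUE)
  band_power <- function(seg) {
    ps <- power_spectrum(seg)
    sel <- ps$frequency_hz > 0 & ps$frequency_hz < cutoff_hz
    10 * log10(sum(10^(ps$power_db[sel] / 10)))
  }
  before <- band_power(audio)
  after <- band_power(filtered)
  invisible(tibble(low_band_db_before = before, low_band_db_after = after,
                   attenuation_db = before - after))
}
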