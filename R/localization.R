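# Leak localization from a microphone-grid sound-intensity matrix: mean
# loudness per grid cell, normalized in the linear power domain to 0..1, with
# the maximum cell taken as the leak site (1 cm resolution at 1 cm step).

#' Construct a sound-intensity matrix from raw loudness values
#'
#' Wraps an existing matrix of per-cell mean loudness (dBA) in the
#' `intensity_matrix` structure used by [normalize_intensity()] and
#' [locate_leak()]; [build_intensity_matrix()] computes the same thing from
#' recordings.
#'
#' @param raw_dba Numeric matrix of mean loudness per grid cell (dBA),
#'   row-major from the upper-left corner.
#' @param step_cm Grid step in cm.
#' @return An `intensity_matrix`.
#' @export
intensity_matrix <- function(raw_dba, step_cm = 1) {
  abort_if(!is.matrix(raw_dba) || !is.numeric(raw_dba) || any(is.na(raw_dba)),
           "`raw_dba` must be a numeric matrix without NAs",
           class = "airleakr_argument_error")
  check_number(step_cm, "step_cm", positive = TRUE)
  structure(
    list(raw_dba = raw_dba, normalized = NULL, step_cm = step_cm,
         origin = "upper-left", traversal = "row-major"),
    class = "intensity_matrix"
  )
}

#' Mean loudness of a point recording
#'
#' Average of the A-weighted SPL series over the first `duration_s` seconds
#' of the recording — the per-cell quantity of the intensity matrix (5 s per
#' grid position in the original protocol).
#'
#' @param segment An [audio_segment()] at least `duration_s` long.
#' @param duration_s Averaging duration in seconds (default 5).
#' @param calibration_offset dB offset passed to [spl_series()].
#' @return Mean level in dBA (scalar).
#' @export
point_loudness <- function(segment, duration_s = 5, calibration_offset = 94) {
  stopifnot(inherits(segment, "audio_segment"))
  check_number(duration_s, "duration_s", positive = TRUE)
  abort_if(duration(segment) < duration_s,
           "segment (", round(duration(segment), 3), " s) shorter than duration_s = ",
           duration_s, class = "airleakr_argument_error")
  seg <- crop(segment, segment$start_time, segment$start_time + duration_s)
  mean(spl_series(seg, calibration_offset = calibration_offset)$dba)
}

#' Build a sound-intensity matrix from grid recordings
#'
#' Takes one recording per grid cell (row-major traversal from the upper-left
#' corner, x rightward, y downward) and fills the raw mean-loudness matrix via
#' [point_loudness()]. Every cell must be present exactly once; missing cells
#' are refused rather than interpolated, since interpolation could fabricate
#' a hotspot.
#'
#' @param recordings A data frame with integer columns `row`, `col` (1-based)
#'   and a list-column `audio` of [audio_segment()]s.
#' @param n_rows,n_cols Grid dimensions; default inferred from `recordings`.
#' @param step_cm Grid step in cm (default 1).
#' @param duration_s,calibration_offset Passed to [point_loudness()].
#' @return An `intensity_matrix` object with fields `raw_dba` (rows x cols),
#'   `normalized` (`NULL` until [normalize_intensity()]), `step_cm`, `origin`
#'   (`"upper-left"`), `traversal` (`"row-major"`).
#' @export
build_intensity_matrix <- function(recordings, n_rows = NULL, n_cols = NULL,
                                   step_cm = 1, duration_s = 5,
                                   calibration_offset = 94) {
  abort_if(!is.data.frame(recordings) ||
             !all(c("row", "col", "audio") %in% names(recordings)),
           "`recordings` needs columns `row`, `col`, `audio`",
           class = "airleakr_argument_error")
  n_rows <- n_rows %||% max(recordings$row)
  n_cols <- n_cols %||% max(recordings$col)
  check_number(step_cm, "step_cm", positive = TRUE)
  want <- paste(rep(seq_len(n_rows), each = n_cols), rep(seq_len(n_cols), n_rows))
  have <- paste(recordings$row, recordings$col)
  dup <- unique(have[duplicated(have)])
  miss <- setdiff(want, have)
  abort_if(length(dup) > 0, "duplicate grid cell(s): ",
           paste0("(", dup, ")", collapse = ", "), class = "airleakr_argument_error")
  abort_if(length(miss) > 0, "missing grid cell(s): ",
           paste0("(", miss, ")", collapse = ", "), class = "airleakr_argument_error")
  raw <- matrix(NA_real_, n_rows, n_cols)
  for (i in seq_len(nrow(recordings))) {
    raw[recordings$row[i], recordings$col[i]] <-
      point_loudness(recordings$audio[[i]], duration_s, calibration_offset)
  }
  structure(
    list(raw_dba = raw, normalized = NULL, step_cm = step_cm,
         origin = "upper-left", traversal = "row-major"),
    class = "intensity_matrix"
  )
}

#' Normalize a sound-intensity matrix
#'
#' Converts the raw dBA matrix to linear acoustic power and divides by the
#' maximum cell power, yielding values in 0..1 with exactly 1.0 at the
#' loudest cell (the convention of the published heatmaps, where 1.00 marks
#' the leak site). Normalization in the power domain makes the scores
#' invariant to any global gain applied to all recordings.
#'
#' @param matrix An `intensity_matrix` from [build_intensity_matrix()].
#' @return The same object with `normalized` filled.
#' @export
normalize_intensity <- function(matrix) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  power <- 10^(matrix$raw_dba / 10)
  abort_if(!any(power > 0) || !all(is.finite(power)),
           "no signal: all cell powers are zero or non-finite",
           class = "airleakr_analysis_error")
  matrix$normalized <- power / max(power)
  matrix
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix: %d x %d, step %g cm, origin %s%s>\n",
              nrow(x$raw_dba), ncol(x$raw_dba), x$step_cm, x$origin,
              if (is.null(x$normalized)) ", raw only" else ", normalized"))
  if (!is.null(x$normalized)) print(round(x$normalized, 2))
  invisible(x)
}

#' @export
as_tibble.intensity_matrix <- function(x, ...) {
  out <- tidyr::expand_grid(row = seq_len(nrow(x$raw_dba)),
                            col = seq_len(ncol(x$raw_dba)))
  out$x_cm <- (out$col - 1) * x$step_cm
  out$y_cm <- (out$row - 1) * x$step_cm
  out$raw_dba <- x$raw_dba[cbind(out$row, out$col)]
  out$normalized <- if (is.null(x$normalized)) NA_real_ else
    x$normalized[cbind(out$row, out$col)]
  out
}

#' Locate the leak as the intensity-matrix maximum
#'
#' The leak site is the cell with the maximum normalized intensity. Exact
#' ties are broken toward the smallest (row, col) and flagged. Cell centers
#' are reported in cm with the upper-left cell at (0, 0), x rightward along
#' columns, y downward along rows.
#'
#' @param matrix An `intensity_matrix`; normalized automatically if needed.
#' @return A `leak_location` tibble: `row`, `col`, `x_cm`, `y_cm`,
#'   `peak_normalized_intensity`, `tie`.
#' @export
locate_leak <- function(matrix) {
  stopifnot(inherits(matrix, "intensity_matrix"))
  if (is.null(matrix$normalized)) matrix <- normalize_intensity(matrix)
  nm <- matrix$normalized
  hits <- which(nm == max(nm), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  out <- tibble(
    row = as.integer(hits[1, 1]), col = as.integer(hits[1, 2]),
    x_cm = unname((hits[1, 2] - 1) * matrix$step_cm),
    y_cm = unname((hits[1, 1] - 1) * matrix$step_cm),
    peak_normalized_intensity = max(nm),
    tie = nrow(hits) > 1
  )
  class(out) <- c("leak_location", class(out))
  out
}

#' Euclidean localization error
#'
#' Distance in cm between an estimated leak location (cell center) and the
#' true source position in the same grid coordinate frame.
#'
#' @param estimate A `leak_location` from [locate_leak()].
#' @param truth_position_cm Numeric `c(x, y)` of the true source in cm.
#' @return Error in cm.
#' @export
localization_error <- function(estimate, truth_position_cm) {
  stopifnot(inherits(estimate, "leak_location"), length(truth_position_cm) == 2)
  unname(sqrt((estimate$x_cm - truth_position_cm[1])^2 +
                (estimate$y_cm - truth_position_cm[2])^2))
}
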