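# Breath segmentation from the airway-pressure trace, pressure-loudness
# correlation, per-phase loudness slopes, and severity grading.

# peak prominence on a sampled trace: height above the higher of the two
# valley floors separating the peak from strictly higher terrain (or the
# trace edge); equal-height plateau samples do not bound a peak
peak_prominences <- function(p, peaks) {
  vapply(peaks, function(i) {
    left <- if (i > 1) p[1:(i - 1)] else numeric()
    right <- if (i < length(p)) p[(i + 1):length(p)] else numeric()
    valley_min <- function(v) if (length(v)) min(v) else p[i]
    higher_l <- which(left > p[i])
    base_l <- if (length(higher_l)) {
      j <- max(higher_l)
      valley_min(if (j < length(left)) left[(j + 1):length(left)] else numeric())
    } else valley_min(left)
    higher_r <- which(right > p[i])
    base_r <- if (length(higher_r)) {
      j <- min(higher_r)
      valley_min(if (j > 1) right[1:(j - 1)] else numeric())
    } else valley_min(right)
    p[i] - max(base_l, base_r)
  }, numeric(1))
}

#' Segment a pressure trace into breaths
#'
#' Inspiratory peaks are found by prominence; breath boundaries are the
#' pressure minima between consecutive peaks (trace ends for the first and
#' last breath). The inspiratory plateau of each breath is the contiguous run
#' of samples at or above 90% of that breath's peak pressure — the window
#' from which leak spectra are extracted.
#'
#' @param trace A [pressure_trace()] spanning at least one breath.
#' @param min_prominence Minimum peak prominence in cmH2O (default 2).
#' @param plateau_fraction Plateau threshold as a fraction of the breath peak
#'   (default 0.9).
#' @return A `breath_segmentation` tibble with columns `breath`, `t_start`,
#'   `t_peak`, `t_end`, `peak_pressure`, `plateau_t0`, `plateau_t1`.
#' @export
detect_breaths <- function(trace, min_prominence = 2, plateau_fraction = 0.9) {
  stopifnot(inherits(trace, "pressure_trace"))
  check_number(min_prominence, "min_prominence", positive = TRUE)
  t <- trace$time_s
  p <- trace$pressure_cmh2o
  n <- length(p)
  abort_if(n < 3, "trace too short to segment", class = "airleakr_argument_error")
  cand <- which(c(FALSE, p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] >= p[3:n], FALSE))
  if (length(cand)) cand <- cand[peak_prominences(p, cand) >= min_prominence]
  abort_if(length(cand) == 0, "no pressure peak with prominence >= ",
           min_prominence, " cmH2O", class = "airleakr_analysis_error")
  # boundaries: minimum between consecutive peaks; trace ends outside
  bounds <- c(1L, vapply(seq_len(length(cand) - 1L), function(j) {
    seg <- cand[j]:cand[j + 1]
    seg[which.min(p[seg])]
  }, integer(1)), n)
  rows <- lapply(seq_along(cand), function(j) {
    i0 <- bounds[j]; i1 <- bounds[j + 1]; ip <- cand[j]
    thr <- plateau_fraction * p[ip]
    lo <- ip; while (lo > i0 && p[lo - 1] >= thr) lo <- lo - 1
    hi <- ip; while (hi < i1 && p[hi + 1] >= thr) hi <- hi + 1
    tibble(breath = j, t_start = t[i0], t_peak = t[ip], t_end = t[i1],
           peak_pressure = p[ip], plateau_t0 = t[lo], plateau_t1 = t[hi])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("breath_segmentation", class(out))
  out
}

#' Percent decline in peak inspiratory pressure
#'
#' `100 * (baseline - injured) / baseline`: the pressure drop that signals
#' loss of airway integrity after a pleural defect (e.g. 16.2 to 9.9 cmH2O is
#' a 39% decline).
#'
#' @param baseline_peak Pre-injury peak inspiratory pressure in cmH2O (> 0).
#' @param injured_peak Post-injury peak inspiratory pressure in cmH2O.
#' @return Decline in percent (not rounded).
#' @export
peak_pressure_decline <- function(baseline_peak, injured_peak) {
  check_number(baseline_peak, "baseline_peak", positive = TRUE)
  check_number(injured_peak, "injured_peak")
  100 * (baseline_peak - injured_peak) / baseline_peak
}

#' Correlate loudness with airway pressure
#'
#' Both series are linearly interpolated onto a common time grid over their
#' overlap, min-max normalized to 0..1, and their Pearson correlation
#' computed. A strong positive correlation is the signature of a
#' pressure-driven leak sound.
#'
#' @param spl An `spl_series` from [spl_series()].
#' @param trace A [pressure_trace()] overlapping `spl` in time.
#' @param common_rate_hz Common resampling grid rate in Hz (default 20:
#'   above breathing rates, below the SPL hop rate ambiguity).
#' @return A `correlation_result` tibble: `rho`, `n_pairs`, `common_rate_hz`.
#' @export
correlate_spl_pressure <- function(spl, trace, common_rate_hz = 20) {
  stopifnot(inherits(spl, "spl_series"), inherits(trace, "pressure_trace"))
  check_number(common_rate_hz, "common_rate_hz", positive = TRUE)
  t0 <- max(min(spl$time_s), min(trace$time_s))
  t1 <- min(max(spl$time_s), max(trace$time_s))
  abort_if(t1 <= t0, "series do not overlap in time", class = "airleakr_argument_error")
  grid <- seq(t0, t1, by = 1 / common_rate_hz)
  abort_if(length(grid) < 3, "overlap too short (< 3 grid points)",
           class = "airleakr_argument_error")
  norm01 <- function(x, what) {
    r <- range(x)
    abort_if(r[1] == r[2], what, " has zero variance; correlation undefined",
             class = "airleakr_analysis_error")
    (x - r[1]) / (r[2] - r[1])
  }
  s <- norm01(approx(spl$time_s, spl$dba, xout = grid)$y, "SPL series")
  p <- norm01(approx(trace$time_s, trace$pressure_cmh2o, xout = grid)$y, "pressure trace")
  out <- tibble(rho = cor(s, p), n_pairs = length(grid),
                common_rate_hz = common_rate_hz)
  class(out) <- c("correlation_result", class(out))
  out
}

#' Loudness slopes during inspiration and expiration
#'
#' Per breath, the OLS slope of SPL against time is computed separately for
#' the inspiratory phase (breath start to pressure peak) and the expiratory
#' phase (peak to breath end), then averaged across breaths. Leak loudness
#' rises faster during inspiration than it falls during expiration.
#'
#' @param spl An `spl_series`.
#' @param seg A `breath_segmentation` from [detect_breaths()].
#' @return A tibble with `inspiration_dba_per_s`, `expiration_dba_per_s`,
#'   `n_breaths` (breaths contributing to both phases).
#' @export
phase_slopes <- function(spl, seg) {
  stopifnot(inherits(spl, "spl_series"), inherits(seg, "breath_segmentation"))
  slope_in <- function(t0, t1) {
    i <- spl$time_s >= t0 & spl$time_s <= t1
    if (sum(i) < 2) return(NA_real_)
    unname(coef(lm(dba ~ time_s, data = spl[i, ]))["time_s"])
  }
  insp <- mapply(slope_in, seg$t_start, seg$t_peak)
  expi <- mapply(slope_in, seg$t_peak, seg$t_end)
  ok <- !is.na(insp) & !is.na(expi)
  if (any(!ok)) {
    warning(sum(!ok), " breath(es) shorter than 2 SPL samples per phase; skipped")
  }
  abort_if(!any(ok), "no breath has >= 2 SPL samples in both phases",
           class = "airleakr_analysis_error")
  tibble(
    inspiration_dba_per_s = mean(insp[ok]),
    expiration_dba_per_s = mean(expi[ok]),
    n_breaths = sum(ok)
  )
}

#' Severity grading thresholds
#'
#' Default cut-points for [classify_severity()]. The dBA-to-severity mapping
#' is calibration-dependent (it was established on one large-animal setup),
#' so cut-points are shipped as an explicit, documented preset rather than
#' constants: below `mild_max_dba` is mild, `mild_max_dba` up to (but not
#' including) `moderate_max_dba` is moderate, and at or above
#' `moderate_max_dba` is severe. A plateau level within `margin_dba` of
#' baseline is classed as no leak.
#'
#' @param margin_dba Detection margin above baseline in dBA (default 3).
#' @param mild_max_dba Upper dBA bound of the mild class (default 58).
#' @param moderate_max_dba Upper dBA bound of the moderate class (default 65).
#' @return A named list of thresholds.
#' @export
severity_thresholds <- function(margin_dba = 3, mild_max_dba = 58,
                                moderate_max_dba = 65) {
  abort_if(!(mild_max_dba < moderate_max_dba),
           "severity cut-points must be strictly increasing",
           class = "airleakr_config_error")
  check_number(margin_dba, "margin_dba", positive = TRUE)
  list(margin_dba = margin_dba, mild_max_dba = mild_max_dba,
       moderate_max_dba = moderate_max_dba)
}

#' Classify air-leak severity from plateau loudness
#'
#' Grades a leak by its mean plateau SPL relative to baseline: `none` when
#' the plateau level is within the detection margin of baseline, otherwise
#' binned by the configured dBA cut-points. A level exactly at a cut-point is
#' assigned to the higher class. The report carries all raw numbers so the
#' class is auditable.
#'
#' @param plateau_spl_dba Mean SPL over inspiratory plateaus, dBA.
#' @param baseline_spl_dba Baseline (no-leak or quiet-phase) SPL, dBA.
#' @param thresholds A list from [severity_thresholds()].
#' @param volume_loss_ml_per_breath Optional measured tidal-volume loss
#'   (ml/breath) from ventilator data; never inferred from sound.
#' @param phase_slopes Optional one-row tibble from [phase_slopes()].
#' @return A `severity_report` tibble with the inputs and an ordered factor
#'   `severity_class` in none < mild < moderate < severe.
#' @export
classify_severity <- function(plateau_spl_dba, baseline_spl_dba,
                              thresholds = severity_thresholds(),
                              volume_loss_ml_per_breath = NA_real_,
                              phase_slopes = NULL) {
  check_number(plateau_spl_dba, "plateau_spl_dba")
  check_number(baseline_spl_dba, "baseline_spl_dba")
  abort_if(!is.list(thresholds) ||
             !all(c("margin_dba", "mild_max_dba", "moderate_max_dba") %in% names(thresholds)) ||
             !(thresholds$mild_max_dba < thresholds$moderate_max_dba),
           "invalid `thresholds`; see severity_thresholds()",
           class = "airleakr_config_error")
  cls <- if (plateau_spl_dba <= baseline_spl_dba + thresholds$margin_dba) {
    "none"
  } else if (plateau_spl_dba < thresholds$mild_max_dba) {
    "mild"
  } else if (plateau_spl_dba < thresholds$moderate_max_dba) {
    "moderate"
  } else {
    "severe"
  }
  out <- tibble(
    plateau_spl_dba = plateau_spl_dba,
    baseline_spl_dba = baseline_spl_dba,
    volume_loss_ml_per_breath = volume_loss_ml_per_breath,
    severity_class = factor(cls, levels = c("none", "mild", "moderate", "severe"),
                            ordered = TRUE),
    inspiration_dba_per_s = if (is.null(phase_slopes)) NA_real_ else
      phase_slopes$inspiration_dba_per_s,
    expiration_dba_per_s = if (is.null(phase_slopes)) NA_real_ else
      phase_slopes$expiration_dba_per_s
  )
  class(out) <- c("severity_report", class(out))
  out
}
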