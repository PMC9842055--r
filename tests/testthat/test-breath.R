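test_that("breath counts match the ventilation rate on synthetic traces", {
  rat <- gen_pressure(rat_scene_config(duration_s = 10))
  n_rat <- nrow(detect_breaths(rat))
  expect_true(n_rat >= 11 && n_rat <= 12)     # 70 bpm over 10 s

  swine <- gen_pressure(swine_scene_config(duration_s = 60))
  expect_equal(nrow(detect_breaths(swine)), 15)  # 15 bpm over 60 s

  flat <- pressure_trace(seq(0, 5, by = 0.01), rep(10, 501))
  expect_error(detect_breaths(flat), "prominence")
})

test_that("breaths are ordered, non-overlapping, with plateaus inside", {
  for (cfg in list(rat_scene_config(duration_s = 6), swine_scene_config(duration_s = 20))) {
    seg <- detect_breaths(gen_pressure(cfg))
    expect_true(all(seg$t_start <= seg$t_peak & seg$t_peak <= seg$t_end))
    expect_true(all(head(seg$t_end, -1) <= tail(seg$t_start, -1) + 1e-9))
    expect_true(all(seg$plateau_t0 >= seg$t_start & seg$plateau_t1 <= seg$t_end))
    expect_true(all(seg$plateau_t0 <= seg$t_peak & seg$plateau_t1 >= seg$t_peak))
  }
})

test_that("a triangular waveform has an essentially empty plateau", {
  cfg <- scene_config(vent = list(bpm = 30, pip = 15, peep = 2,
                                  rise_fraction = 0.5, plateau_fraction = 0),
                      leak = NULL, duration_s = 8)
  tr <- gen_pressure(cfg)
  seg <- detect_breaths(tr)
  dt <- 1 / cfg$pressure_rate_hz
  # threshold 90% of peak: plateau spans at most the tip of the triangle
  expect_true(all(seg$plateau_t1 - seg$plateau_t0 <= 0.1 * (60 / 30) + 2 * dt))
})

test_that("peak-pressure decline follows its closed form", {
  expect_equal(round(peak_pressure_decline(16.2, 9.9)), 39)
  expect_equal(peak_pressure_decline(12, 12), 0)
  expect_equal(peak_pressure_decline(10, 0), 100)
  expect_error(peak_pressure_decline(0, 5), "> 0")
})

test_that("pressure-loudness correlation is exact for affine relations", {
  tr <- gen_pressure(swine_scene_config(duration_s = 12))
  spl_t <- seq(0.1, 11.9, by = 0.05)
  p_at <- approx(tr$time_s, tr$pressure_cmh2o, xout = spl_t)$y
  mk_spl <- function(v) {
    out <- tibble::tibble(time_s = spl_t, dba = v)
    class(out) <- c("spl_series", class(out))
    out
  }
  expect_equal(correlate_spl_pressure(mk_spl(3 * p_at + 40), tr)$rho, 1, tolerance = 1e-6)
  expect_equal(correlate_spl_pressure(mk_spl(-p_at), tr)$rho, -1, tolerance = 1e-6)
  expect_error(correlate_spl_pressure(mk_spl(rep(50, length(spl_t))), tr),
               "zero variance")
})

test_that("correlation is invariant to affine rescaling of either series", {
  cfg <- swine_scene_config(duration_s = 8, seed = 4)
  sc <- gen_scene(cfg)
  spl <- spl_series(sc$audio)
  tr <- sc$truth$pressure
  rho0 <- correlate_spl_pressure(spl, tr)$rho
  spl2 <- spl; spl2$dba <- 2.5 * spl$dba - 7
  class(spl2) <- class(spl)
  tr2 <- pressure_trace(tr$time_s, 0.3 * tr$pressure_cmh2o + 11)
  expect_equal(correlate_spl_pressure(spl2, tr)$rho, rho0, tolerance = 1e-9)
  expect_equal(correlate_spl_pressure(spl, tr2)$rho, rho0, tolerance = 1e-9)
})

test_that("low-noise leak scenes give a strong pressure-loudness correlation", {
  # leak gain tracks pressure; ambient 20 dB below the leak plateau level
  for (seed in 1:3) {
    cfg <- swine_scene_config(duration_s = 12, seed = seed,
                              ambient_level_db = -70)
    sc <- gen_scene(cfg)
    rho <- correlate_spl_pressure(spl_series(sc$audio), sc$truth$pressure)$rho
    expect_gte(rho, 0.9)
  }
})

test_that("phase slopes recover a known sawtooth within 2 percent", {
  # one 2 s breath: SPL rises 24.84 dBA/s for 1 s then falls 14.53 dBA/s
  t <- seq(0, 2, by = 0.02)
  dba <- ifelse(t <= 1, 40 + 24.84 * t, 40 + 24.84 - 14.53 * (t - 1))
  spl <- tibble::tibble(time_s = t, dba = dba)
  class(spl) <- c("spl_series", class(spl))
  seg <- tibble::tibble(breath = 1L, t_start = 0, t_peak = 1, t_end = 2,
                        peak_pressure = 16, plateau_t0 = 0.9, plateau_t1 = 1.1)
  class(seg) <- c("breath_segmentation", class(seg))
  sl <- phase_slopes(spl, seg)
  expect_equal(sl$inspiration_dba_per_s, 24.84, tolerance = 0.02 * 24.84)
  expect_equal(sl$expiration_dba_per_s, -14.53, tolerance = 0.02 * 14.53)

  const <- spl; const$dba <- rep(50, nrow(const)); class(const) <- class(spl)
  sl0 <- phase_slopes(const, seg)
  expect_equal(sl0$inspiration_dba_per_s, 0, tolerance = 1e-9)
  expect_equal(sl0$expiration_dba_per_s, 0, tolerance = 1e-9)
})

test_that("inspiration is steeper than expiration in generated scenes", {
  cfg <- swine_scene_config(duration_s = 8, seed = 6)
  sc <- gen_scene(cfg)
  seg <- detect_breaths(sc$truth$pressure)
  sl <- phase_slopes(spl_series(sc$audio), seg)
  expect_gt(sl$inspiration_dba_per_s, 0)
  expect_lt(sl$expiration_dba_per_s, 0)
  expect_gt(sl$inspiration_dba_per_s, abs(sl$expiration_dba_per_s))
})

test_that("severity classes follow the documented margins and tie rule", {
  th <- severity_thresholds(margin_dba = 3, mild_max_dba = 58, moderate_max_dba = 65)
  cls <- function(p, b = 40) as.character(classify_severity(p, b, th)$severity_class)
  expect_equal(cls(40, 40), "none")
  expect_equal(cls(42.9, 40), "none")      # inside the margin
  expect_equal(cls(50, 40), "mild")
  expect_equal(cls(58, 40), "moderate")    # exact cut-point: higher class
  expect_equal(cls(65, 40), "severe")
  expect_equal(cls(70, 40), "severe")
  expect_error(severity_thresholds(mild_max_dba = 70, moderate_max_dba = 60),
               "increasing")
  expect_error(classify_severity(50, 40, list(margin_dba = 3, mild_max_dba = 70,
                                              moderate_max_dba = 60)),
               "thresholds")
})

test_that("severity is monotone in generator leak strength", {
  plateau_spl <- function(strength) {
    sc <- gen_scene(swine_scene_config(duration_s = 8, leak_strength = strength,
                                       seed = 5))
    seg <- detect_breaths(sc$truth$pressure)
    spl <- spl_series(sc$audio)
    keep <- rep(FALSE, nrow(spl))
    for (i in seq_len(nrow(seg))) {
      keep <- keep | (spl$time_s >= seg$plateau_t0[i] & spl$time_s <= seg$plateau_t1[i])
    }
    mean(spl$dba[keep])
  }
  levels <- vapply(c(1, 8, 15), plateau_spl, numeric(1))
  expect_true(all(diff(levels) > 0))
  # the two mild-leak settings of the severity experiment keep their order
  expect_lt(levels[2], levels[3])
  classes <- vapply(levels, function(p)
    as.integer(classify_severity(p, levels[1])$severity_class), integer(1))
  expect_true(all(diff(classes) >= 0))
})
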