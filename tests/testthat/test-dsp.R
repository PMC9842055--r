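test_that("A-weighting matches the standard curve", {
  expect_equal(a_weighting_gain(1000), 0, tolerance = 0.01)
  expect_equal(a_weighting_gain(100), -19.1, tolerance = 0.1)
  expect_equal(a_weighting_gain(10000), -2.5, tolerance = 0.1)
  expect_error(a_weighting_gain(0), "positive")
  # unimodal with maximum near 2.5 kHz
  f <- seq(100, 15000, by = 10)
  g <- a_weighting_gain(f)
  expect_lt(abs(f[which.max(g)] - 2500), 300)
  expect_equal(sum(diff(sign(diff(g))) != 0), 1)
})

test_that("frequency-domain A-weighting shapes tone power by the curve", {
  for (freq in c(100, 1000, 5000)) {
    seg <- tone(freq, rate = 44100, dur = 0.5, amp = 0.5)
    shift <- rms_db(apply_a_weighting(seg)) - rms_db(seg)
    expect_equal(shift, a_weighting_gain(freq), tolerance = 0.5)
  }
  z <- audio_segment(numeric(1000), 8000)
  expect_true(all(apply_a_weighting(z)$samples == 0))
})

test_that("SPL of a full-scale 1 kHz sine is offset minus 3.01 dB", {
  seg <- tone(1000, rate = 44100, dur = 1)
  spl <- spl_series(seg, calibration_offset = 94)
  # sine RMS = 1/sqrt(2); A-weighting at 1 kHz is 0 dB
  expect_equal(mean(spl$dba), 94 - 20 * log10(sqrt(2)), tolerance = 0.05)
})

test_that("doubling amplitude raises every SPL window by 6.02 dB", {
  withr::with_seed(1, x <- 0.2 * rnorm(22050))
  a <- spl_series(audio_segment(x, 22050))
  b <- spl_series(audio_segment(2 * x, 22050))
  expect_equal(b$dba - a$dba, rep(20 * log10(2), nrow(a)), tolerance = 1e-9)
})

test_that("spl_series equals the brute-force windowed-RMS oracle", {
  withr::with_seed(3, x <- 0.3 * rnorm(16000))
  seg <- audio_segment(x, 16000)
  spl <- spl_series(seg, window_s = 0.125, hop_s = 0.03125,
                    calibration_offset = 94, a_weight = FALSE)
  oracle <- brute_spl(x, 16000, 0.125, 0.03125, 94)
  expect_equal(spl$dba, oracle, tolerance = 1e-9)
  expect_error(spl_series(audio_segment(x[1:100], 16000)), "shorter")
})

test_that("spectrogram places a pure tone on a single stationary ridge", {
  seg <- tone(1223, rate = 22050, dur = 1, amp = 0.5)
  sg <- spectrogram(seg)
  ridge <- apply(sg$power_db, 1, which.max)
  bin_hz <- sg$frequency_hz[2] - sg$frequency_hz[1]
  expect_true(all(abs(sg$frequency_hz[ridge] - 1223) <= bin_hz))
  # stationary: ridge level constant within 1 dB away from the edges
  peaks <- apply(sg$power_db, 1, max)
  inner <- peaks[2:(length(peaks) - 1)]
  expect_lt(max(inner) - min(inner), 1)
})

test_that("spectrogram of silence sits at the floor and two tones keep ratio 2", {
  z <- spectrogram(audio_segment(numeric(8000), 8000), floor_db = -100)
  expect_true(all(z$power_db == -100))
  two <- mix_signals(tone(665, 8000, 1, 0.3), tone(1330, 8000, 1, 0.2))
  b <- detect_bands(power_spectrum(two), -40, 200, 0, 4000)
  expect_equal(nrow(b), 2)
  expect_equal(b$center_hz[2] / b$center_hz[1], 2, tolerance = 0.02)
})

test_that("power spectrum peaks at the tone frequency and is flat for noise", {
  seg <- tone(5020, rate = 22050, dur = 1, amp = 0.5)
  ps <- power_spectrum(seg)
  bin_hz <- ps$frequency_hz[2] - ps$frequency_hz[1]
  expect_lt(abs(ps$frequency_hz[which.max(ps$power_db)] - 5020), bin_hz + 1e-9)

  withr::with_seed(5, noise <- audio_segment(0.1 * rnorm(22050 * 4), 22050))
  psn <- power_spectrum(noise, n_fft = 256)   # heavy averaging
  mid <- psn$power_db[psn$frequency_hz > 500 & psn$frequency_hz < 10000]
  expect_lt(max(mid) - min(mid), 6)           # +/- 3 dB about the mean

  z <- power_spectrum(audio_segment(numeric(4096), 8000))
  expect_equal(length(unique(z$power_db)), 1)
  expect_error(power_spectrum(seg, 0.5, 0.5), "greater")
})

test_that("zero-phase high-pass meets its attenuation contract", {
  low <- tone(200, 22050, 1, 0.5)
  expect_lt(rms_db(highpass(low, 500, 4)) - rms_db(low), -30)
  high <- tone(2000, 22050, 1, 0.5)
  mid <- function(seg) crop(seg, 0.2, 0.8)    # avoid edge transients
  expect_equal(rms_db(mid(highpass(high, 500, 4))), rms_db(mid(high)),
               tolerance = 1)
  expect_error(highpass(low, 22050 / 2), "Nyquist")
})

test_that("high-pass is passive and repeated passes steepen the response", {
  withr::with_seed(11, x <- audio_segment(0.3 * rnorm(22050), 22050))
  once <- highpass(x, 500, 4)
  twice <- highpass(once, 500, 4)
  band_db <- function(seg, f0, f1) {
    ps <- power_spectrum(seg)
    sel <- ps$frequency_hz >= f0 & ps$frequency_hz < f1
    10 * log10(sum(10^(ps$power_db[sel] / 10)))
  }
  for (band in list(c(0, 250), c(250, 500), c(500, 2000), c(2000, 10000))) {
    expect_lte(band_db(once, band[1], band[2]), band_db(x, band[1], band[2]) + 0.1)
    expect_lte(band_db(twice, band[1], band[2]), band_db(once, band[1], band[2]) + 0.1)
  }
  expect_lt(band_db(twice, 0, 250), band_db(once, 0, 250))
})

test_that("filtering a heart + leak mixture removes heart power, keeps band centers", {
  cfg <- swine_scene_config(duration_s = 4, seed = 9)
  leak <- gen_leak_sound(cfg)
  heart_cfg <- heart_scene_config(duration_s = 4, seed = 9)
  heart <- gen_heart_sound(heart_cfg)
  heart <- resample_audio(heart, cfg$sample_rate)
  mixed <- mix_signals(leak, heart, 1, 0.02)
  filtered <- highpass(mixed, 500, 4)
  # residual heart-band power below 1% of its input power
  band_power <- function(seg, f0, f1) {
    ps <- power_spectrum(seg)
    sel <- ps$frequency_hz >= f0 & ps$frequency_hz < f1
    sum(10^(ps$power_db[sel] / 10))
  }
  expect_lt(band_power(filtered, 20, 400), 0.01 * band_power(mixed, 20, 400))
  # leak band centers unchanged
  b_in <- detect_bands(power_spectrum(leak), -60, 200, 500, 5000)
  b_out <- detect_bands(power_spectrum(filtered), -60, 200, 500, 5000)
  expect_equal(b_out$center_hz, b_in$center_hz, tolerance = 1e-2)
})

test_that("mixing follows the weighted-sum contract", {
  a <- tone(440, 8000, 0.5, 0.4)
  zeros <- audio_segment(numeric(4000), 8000)
  expect_equal(mix_signals(a, zeros)$samples, a$samples)
  doubled <- mix_signals(a, a, 1, 1)
  expect_equal(doubled$samples, 2 * a$samples)   # no clipping at 0.8 peak
  loud <- mix_signals(tone(440, 8000, 0.5, 0.9), tone(440, 8000, 0.5, 0.9))
  expect_equal(max(abs(loud$samples)), 1)        # peak-normalized
  expect_error(mix_signals(a, tone(440, 16000, 0.5)), "rates differ")
})

test_that("power-density histogram conserves counts across bin widths", {
  cfg <- swine_scene_config(duration_s = 4, seed = 2)
  ps <- power_spectrum(gen_scene(cfg)$audio)
  for (w in c(1, 2.5, 5, 10)) {
    h <- power_density_histogram(ps, w)
    expect_equal(sum(h$count), nrow(ps))
  }
  flat <- synthetic_spectrum(numeric(0), numeric(0), floor_db = -90)
  h1 <- power_density_histogram(flat, 5)
  expect_equal(sum(h1$count > 0), 1)
  expect_error(power_density_histogram(ps, 0), "> 0")
})

test_that("high-pass filtering strips the low-power-density mass of a mixture", {
  cfg <- swine_scene_config(duration_s = 4, seed = 13)
  leak <- gen_leak_sound(cfg)
  heart <- resample_audio(gen_heart_sound(heart_scene_config(duration_s = 4)),
                          cfg$sample_rate)
  mixed <- mix_signals(leak, heart, 1, 0.05)
  filtered <- highpass(mixed, 500, 4)
  ps_m <- power_spectrum(mixed)
  ps_f <- power_spectrum(filtered)
  low <- ps_m$frequency_hz < 400
  # the heart contribution dominates below 400 Hz and is removed
  expect_gt(sum(10^(ps_m$power_db[low] / 10)), 100 * sum(10^(ps_f$power_db[low] / 10)))
})
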