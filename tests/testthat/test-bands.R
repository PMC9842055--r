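test_that("seven peaks above threshold yield seven labeled bands", {
  freqs <- c(890, 1223, 2524, 3670, 5020, 6100, 8845)
  ps <- synthetic_spectrum(freqs, peak_db = seq(-48, -70, length.out = 7))
  b <- detect_bands(ps, threshold_db = -80, min_separation_hz = 200,
                    fmin = 0, fmax = 10000)
  expect_equal(nrow(b), 7)
  expect_equal(b$label, paste0("fb", 1:7))
  expect_equal(b$center_hz, freqs, tolerance = 5)
  expect_true(all(diff(b$center_hz) >= 200))
})

test_that("a flat spectrum below threshold yields an empty band table", {
  ps <- synthetic_spectrum(numeric(0), numeric(0), floor_db = -100)
  b <- detect_bands(ps, -80, 200, 0, 10000)
  expect_equal(nrow(b), 0)
  expect_s3_class(b, "frequency_bands")
})

test_that("peaks closer than the separation merge into the stronger band", {
  ps <- synthetic_spectrum(c(1000, 1050), c(-50, -55), width_hz = 10)
  b <- detect_bands(ps, -80, min_separation_hz = 200, fmin = 0, fmax = 10000)
  expect_equal(nrow(b), 1)
  expect_lt(abs(b$center_hz - 1000), 25)
  # brute-force check: with a tiny separation both survive
  b2 <- detect_bands(ps, -80, min_separation_hz = 10, fmin = 0, fmax = 10000)
  expect_equal(nrow(b2), 2)
})

test_that("band count is monotone non-increasing in threshold and separation", {
  cfg <- rat_scene_config(seed = 21)
  sc <- gen_scene(cfg)
  seg <- detect_breaths(sc$truth$pressure)
  ps <- power_spectrum(sc$audio, seg$plateau_t0[2], seg$plateau_t1[2])
  counts_thr <- vapply(c(-90, -80, -70, -60, -50),
                       function(th) nrow(detect_bands(ps, th, 200, 0, 10000)),
                       numeric(1))
  expect_true(all(diff(counts_thr) <= 0))
  counts_sep <- vapply(c(50, 200, 500, 1000),
                       function(s) nrow(detect_bands(ps, -80, s, 0, 10000)),
                       numeric(1))
  expect_true(all(diff(counts_sep) <= 0))
})

test_that("harmonic numbers reproduce the observed band ratios", {
  expect_equal(harmonic_number(8845, 1223, 0.25), 7L)
  expect_equal(harmonic_number(2731, 665, 0.25), 4L)
  expect_equal(harmonic_number(1355, 665, 0.25), 2L)
  expect_equal(harmonic_number(1223, 1223, 0.01), 1L)
  expect_true(is.na(harmonic_number(890, 1223, 0.25)))   # ratio 0.73: no integer
  expect_true(is.na(harmonic_number(1850, 1223, 0.25)))  # ratio 1.51
  expect_error(harmonic_number(1000, 0), "> 0")
})

test_that("the series fit excludes the ventilator band and tolerates gaps", {
  mk_bands <- function(centers, powers = seq(-45, by = -4, length.out = length(centers))) {
    b <- tibble::tibble(label = paste0("fb", seq_along(centers)),
                        center_hz = centers, peak_power_db = powers,
                        bandwidth_hz = 10)
    class(b) <- c("frequency_bands", class(b))
    b
  }
  rat <- find_harmonic_series(mk_bands(c(890, 1223, 2524, 5020, 8845)))
  expect_equal(rat$fundamental_hz, 1223)
  expect_equal(rat$members$harmonic_number, c(1L, 2L, 4L, 7L))
  expect_equal(rat$excluded$center_hz, 890)

  swine <- find_harmonic_series(mk_bands(c(665, 1355, 2731)))
  expect_equal(swine$fundamental_hz, 665)
  expect_equal(swine$members$harmonic_number, c(1L, 2L, 4L))
  expect_equal(nrow(swine$excluded), 0)

  exact <- find_harmonic_series(mk_bands(c(500, 1000, 1500)))
  expect_equal(exact$fundamental_hz, 500)
  expect_equal(exact$members$harmonic_number, 1:3)

  expect_error(find_harmonic_series(mk_bands(c(500, 777, 1234)), tolerance = 0.01),
               "best candidate")
  expect_error(find_harmonic_series(mk_bands(c(500, 1000))), "at least 3")
})

test_that("band-power regression recovers exact linear relationships", {
  # points generated exactly on the two reported intensity-frequency lines
  cases <- list(
    list(freqs = c(1223, 2524, 3670, 5020, 6100, 8845), slope = -0.00231, int = -49.1),
    list(freqs = c(665, 1355, 2030, 2731), slope = -0.00792, int = -34.8)
  )
  for (cs in cases) {
    b <- tibble::tibble(center_hz = cs$freqs,
                        peak_power_db = cs$slope * cs$freqs + cs$int)
    fit <- band_power_regression(b)
    expect_equal(fit$slope, cs$slope, tolerance = 1e-12)
    expect_equal(fit$intercept, cs$int, tolerance = 1e-9)
    expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("regression equals the closed-form OLS oracle on noisy data", {
  withr::with_seed(17, {
    x <- runif(8, 500, 9000)
    y <- -0.003 * x - 50 + rnorm(8, sd = 2)
  })
  fit <- band_power_regression(tibble::tibble(center_hz = x, peak_power_db = y))
  oracle <- ols_oracle(x, y)
  expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-9)
  expect_equal(fit$intercept, unname(oracle["intercept"]), tolerance = 1e-9)
})

test_that("regression handles degenerate inputs explicitly", {
  flat <- tibble::tibble(center_hz = c(500, 1000, 1500), peak_power_db = -50)
  fit <- band_power_regression(flat)
  expect_equal(fit$slope, 0)
  expect_equal(fit$r_squared, 0)
  expect_error(band_power_regression(flat[1:2, ]), ">= 3")
  same_f <- tibble::tibble(center_hz = rep(500, 3), peak_power_db = c(-50, -51, -52))
  expect_error(band_power_regression(same_f), "identical")
})

test_that("tidy and glance expose the regression as tidy tibbles", {
  b <- tibble::tibble(center_hz = c(665, 1355, 2030, 2731),
                      peak_power_db = -0.00792 * c(665, 1355, 2030, 2731) - 34.8 +
                        c(0.1, -0.1, 0.05, -0.05))
  fit <- band_power_regression(b)
  td <- tidy(fit)
  expect_equal(td$term, c("intercept", "slope"))
  expect_equal(td$estimate[2], fit$slope)
  gl <- glance(fit)
  expect_equal(gl$n, 4)
  expect_gt(gl$r.squared, 0.99)
})
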