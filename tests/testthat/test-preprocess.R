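test_that("RMS envelope matches closed forms and is scale-equivariant", {
  # constant signal -> |c| everywhere
  x <- emg_signal(matrix(-3, 200, 2), 100)
  expect_equal(rms_envelope(x, 100)$samples, matrix(3, 200, 2))
  # zero in, zero out
  z <- emg_signal(matrix(0, 50, 1), 100)
  expect_equal(rms_envelope(z, 100)$samples, matrix(0, 50, 1))
  # unit sine, window >> period: interior ~ 1/sqrt(2) within 1%
  fs <- 1000
  s <- emg_signal(sin(2 * pi * 50 * (0:1999) / fs), fs)
  env <- rms_envelope(s, 200)  # 200 ms = 10 periods
  interior <- env$samples[300:1700, 1]
  expect_true(all(abs(interior - 1 / sqrt(2)) < 0.01 / sqrt(2)))
  # scale equivariance rms(k x) = |k| rms(x)
  x2 <- make_signal(n = 300, c = 2, seed = 3)
  expect_equal(rms_envelope(signal_scale(x2, -2.5), 50)$samples,
               2.5 * rms_envelope(x2, 50)$samples, tolerance = 1e-12)
  # window longer than signal errors
  expect_error(rms_envelope(make_signal(n = 5), 1000), "longer than signal")
})

test_that("zero-phase Butterworth filtering matches analytic responses", {
  fs <- 100
  # DC gain 1 (within 1e-6 relative everywhere, including edges)
  dc <- emg_signal(matrix(2, 400, 1), fs)
  out <- butterworth_filter(dc, "lowpass", fc_hz = 1, order = 1)
  expect_true(max(abs(out$samples - 2)) < 2e-6)
  # sine at 10x cutoff through order-1 lowpass: >= 90% attenuation
  # (analytic zero-phase gain 1/(1 + 100) ~ 0.0099)
  t <- (0:1999) / fs
  s <- emg_signal(sin(2 * pi * 10 * t), fs)
  y <- butterworth_filter(s, "lowpass", fc_hz = 1, order = 1)
  expect_lt(max(abs(y$samples[200:1800, 1])), 0.1)
  # 50 Hz sine through 50 Hz notch: residual < 5%
  fs2 <- 2000
  s2 <- emg_signal(sin(2 * pi * 50 * (0:9999) / fs2), fs2)
  y2 <- butterworth_filter(s2, "notch", notch_hz = 50)
  expect_lt(max(abs(y2$samples[1000:9000, 1])), 0.05)
  # corner at/above Nyquist rejected
  expect_error(butterworth_filter(dc, "lowpass", fc_hz = 60), "Nyquist")
  expect_error(butterworth_filter(dc, "notch", notch_hz = 50), "Nyquist")
})

test_that("zero-phase filtering introduces no lag for a band-interior sine", {
  fs <- 1000
  t <- (0:4095) / fs
  s <- sin(2 * pi * 30 * t)
  y <- butterworth_filter(emg_signal(s, fs), "bandpass", band_hz = c(10, 100),
                          order = 3)$samples[, 1]
  cc <- stats::ccf(s[500:3500], y[500:3500], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("resampling preserves in-band content and enforces its contract", {
  x <- make_signal(n = 500, fs = 100)
  expect_identical(resample_to(x, 100), x)        # identity at target = fs
  expect_error(resample_to(x, 200), "upsampling") # no upsampling
  # 2000 -> 100 Hz on a 1 Hz sine: shape preserved, count / 20
  fs <- 2000
  t <- (0:39999) / fs
  s <- emg_signal(sin(2 * pi * t), fs)
  y <- resample_to(s, 100)
  expect_equal(n_samples(y), 2000)
  expect_equal(y$fs, 100)
  ref <- sin(2 * pi * seq(0, by = 1 / 100, length.out = 2000))
  expect_lt(max(abs(y$samples[, 1] - ref)), 0.02)
})

test_that("every preprocessing step preserves the channel count", {
  x <- make_signal(n = 600, c = 5, fs = 200, seed = 9)
  expect_equal(n_channels(rms_envelope(x, 50)), 5)
  expect_equal(n_channels(butterworth_filter(x, "lowpass", fc_hz = 5)), 5)
  expect_equal(n_channels(butterworth_filter(x, "notch", notch_hz = 50)), 5)
  expect_equal(n_channels(resample_to(x, 100)), 5)
  y <- preprocess_dataset(x, preprocess_config(rms_window_ms = 50,
                                               target_fs_hz = 100))
  expect_equal(n_channels(y), 5)
  expect_equal(y$fs, 100)
  expect_true(all(rms_envelope(x, 50)$samples >= 0))
})

test_that("the high-rate conditioning chain runs end to end", {
  # emulate a noisy 2 kHz recording: 50 Hz interference + wideband activity
  fs <- 2000
  t <- (0:9999) / fs
  set.seed(4)
  raw <- matrix(rnorm(length(t) * 2, sd = 0.5), ncol = 2) +
    0.8 * sin(2 * pi * 50 * t)
  cfg <- preprocess_config(notch_hz = 50, bandpass = c(20, 700, 5),
                           rms_window_ms = 100, target_fs_hz = 100)
  out <- preprocess_dataset(emg_signal(raw, fs), cfg)
  expect_equal(out$fs, 100)
  expect_equal(n_samples(out), 500)
  expect_true(all(is.finite(out$samples)))
})
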