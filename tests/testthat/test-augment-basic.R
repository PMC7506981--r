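test_that("Gaussian noise scales with signal power and respects the seed", {
  # zero signal has zero power, so zero noise
  z <- emg_signal(matrix(0, 100, 2), 100)
  expect_equal(gaussian_noise(z, gn_spec(snr = 30), seed = 1)$samples, z$samples)
  # empirical power ratio near the target (single run, moderate n)
  set.seed(2)
  x <- emg_signal(matrix(rnorm(4e4), ncol = 2), 100)
  y <- gaussian_noise(x, gn_spec(snr = 30), seed = 5)
  noise <- y$samples - x$samples
  ratio <- colMeans(x$samples^2) / colMeans(noise^2)
  expect_true(all(ratio > 27 & ratio < 33))
  # determinism and mean preservation
  y2 <- gaussian_noise(x, gn_spec(snr = 30), seed = 5)
  expect_identical(y$samples, y2$samples)
  expect_lt(abs(mean(noise)), 4 / sqrt(length(noise)))
  # dB interpretation: snr_db = 10 dB is a linear ratio of 10
  ydb <- gaussian_noise(x, gn_spec(snr = 10, snr_db = TRUE), seed = 5)
  rdb <- mean(x$samples^2) / mean((ydb$samples - x$samples)^2)
  expect_equal(rdb, 10, tolerance = 0.15 * 10)
  expect_error(gn_spec(snr = 0), "snr")
})

test_that("per-channel noise power tracks each channel's own power", {
  set.seed(3)
  m <- cbind(rnorm(2e4, sd = 10), rnorm(2e4, sd = 0.1))
  y <- gaussian_noise(emg_signal(m, 100), gn_spec(snr = 30), seed = 7)
  noise <- y$samples - m
  # quiet channel keeps its own SNR instead of drowning in the loud one
  expect_equal(mean(m[, 2]^2) / mean(noise[, 2]^2), 30, tolerance = 3)
  # pooled mode uses one shared power
  yp <- gaussian_noise(emg_signal(m, 100), gn_spec(snr = 30, pooled = TRUE), seed = 7)
  np <- yp$samples - m
  expect_gt(mean(np[, 2]^2), 100 * mean(noise[, 2]^2))
})

test_that("magnitude warping interpolates its knots and degenerates to identity", {
  x <- make_signal(n = 301, c = 3, seed = 4)
  # sigma = 0: exact identity
  expect_identical(magnitude_warp(x, mw_spec(sigma = 0), seed = 1)$samples,
                   x$samples)
  # the spline passes through the drawn knot values: warp a constant-1
  # signal so the output IS the curve, and reproduce the knot draw
  ones <- emg_signal(matrix(1, 301, 1), 100)
  curve <- magnitude_warp(ones, mw_spec(sigma = 0.1, knots = 4), seed = 42)$samples[, 1]
  set.seed(42)
  rk <- rnorm(4, mean = 1, sd = 0.1)
  expect_equal(curve[c(1, 101, 201, 301)], rk, tolerance = 1e-9)
  # one shared curve: output/input ratio is channel-independent
  y <- magnitude_warp(x, mw_spec(sigma = 0.1), seed = 9)
  ratio <- y$samples / x$samples
  expect_equal(ratio[, 1], ratio[, 2], tolerance = 1e-9)
  expect_equal(ratio[, 1], ratio[, 3], tolerance = 1e-9)
  # and the curve is smooth: bounded second difference
  expect_lt(max(abs(diff(ratio[, 1], differences = 2))), 1e-3)
  # per-channel mode draws distinct curves
  yp <- magnitude_warp(x, mw_spec(sigma = 0.1, per_channel = TRUE), seed = 9)
  rp <- yp$samples / x$samples
  expect_gt(max(abs(rp[, 1] - rp[, 2])), 1e-3)
  expect_error(magnitude_warp(make_signal(n = 3), mw_spec(knots = 4)), "knots")
})

test_that("wavelet perturbation is the identity at b = 1 for every wavelet", {
  set.seed(5)
  x <- emg_signal(matrix(rnorm(512 * 2), ncol = 2), 100)
  for (w in supported_wavelets()) {
    lv <- min(3L, max_dwt_level(512, w))
    y <- wavelet_perturb(x, wd_spec(wavelet = w, level = lv, b = 1))
    expect_lt(max(abs(y$samples - x$samples)), 1e-8 * max(abs(x$samples)))
  }
})

test_that("b = 0 removes exactly the detail energy (Parseval)", {
  set.seed(6)
  x <- emg_signal(rnorm(1024), 100)
  for (w in c("db7", "sym4", "coif2")) {
    y <- wavelet_perturb(x, wd_spec(wavelet = w, level = 5, b = 0))
    resid <- sum((x$samples - y$samples)^2)
    dec <- wave_dec(x$samples[, 1], w, 5)
    detail <- sum(vapply(dec$cd, function(c) sum(c^2), 0))
    expect_equal(resid, detail, tolerance = 1e-6)
  }
})

test_that("all three transforms preserve shape and record lineage", {
  ds <- emg_dataset(list(make_record(n = 512, c = 2, gesture = 3, repetition = 2)))
  for (spec in list(gn_spec(), mw_spec(), wd_spec(level = 4))) {
    aug <- build_augmented_dataset(ds, spec, R = 1, seed = 11)
    gen <- aug$records[[2]]
    expect_equal(dim(gen$signal$samples), dim(ds$records[[1]]$signal$samples))
    expect_equal(gen$origin, "augmented")
    expect_equal(gen$lineage, spec$method)
    expect_equal(gen$gesture, 3)       # labels never altered
    expect_equal(gen$repetition, 2)
  }
})
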