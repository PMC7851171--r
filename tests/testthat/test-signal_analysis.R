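test_that("db38 filter bank is orthonormal with perfect reconstruction", {
  lo <- ionobeat:::.db38_lo
  expect_length(lo, 76)
  expect_equal(sum(lo), sqrt(2), tolerance = 1e-12)
  expect_equal(sum(lo^2), 1, tolerance = 1e-12)
  # even-shift orthogonality of the scaling filter
  for (k in c(1, 5, 17)) {
    expect_equal(sum(lo * c(rep(0, 2 * k), lo)[1:76]), 0, tolerance = 1e-10)
  }
  set.seed(2)
  x <- stats::rnorm(2048)
  dec <- ionobeat:::.dwt_per(x, 5)
  xr <- ionobeat:::.idwt_per(dec)
  expect_equal(xr, x, tolerance = 1e-10)
})

test_that("wavelet denoising preserves band-limited signals, kills >10 MHz", {
  # band-limited 2 MHz pulse: energy preserved within 5%
  t <- (0:(2^14 - 1)) / fs_acq
  env <- exp(-(t - 30e-6)^2 / (2 * (2e-6)^2))
  tr <- ia_trace(t, env * sin(2 * pi * 2e6 * t))
  den <- wavelet_denoise(tr)
  expect_equal(sum(den$pressure^2), sum(tr$pressure^2), tolerance = 0.05)
  # 12 MHz content suppressed by >= 20 dB
  tr12 <- ia_trace(t, env * sin(2 * pi * 12e6 * t))
  den12 <- wavelet_denoise(tr12)
  supp <- 20 * log10(sqrt(sum(tr12$pressure^2) / sum(den12$pressure^2)))
  expect_gte(supp, 20)
  # zero in, zero out
  z <- wavelet_denoise(ia_trace(t, numeric(length(t))))
  expect_equal(max(abs(z$pressure)), 0)
})

test_that("wavelet denoising is near-idempotent", {
  t <- (0:(2^14 - 1)) / fs_acq
  set.seed(5)
  raw <- sin(2 * pi * 1.5e6 * t) * exp(-(t - 40e-6)^2 / (2 * (4e-6)^2)) +
    0.2 * stats::rnorm(length(t))
  d1 <- wavelet_denoise(ia_trace(t, raw))
  d2 <- wavelet_denoise(d1)
  rel <- sqrt(sum((d2$pressure - d1$pressure)^2) / sum(d1$pressure^2))
  expect_lt(rel, 0.01)
})

test_that("spectral amplitude recovers sinusoid amplitudes at df = 5 kHz", {
  f0 <- 2.5e6
  n <- 2^14
  t <- (0:(n - 1)) / fs_acq
  tr <- ia_trace(t, 3.7 * sin(2 * pi * f0 * t))
  a <- amplitude_at_frequency(tr, f0, window = c(0, n / fs_acq))
  expect_equal(a$amplitude, 3.7, tolerance = 0.02)
  # frequency resolution honored: evaluation grid spaced 5 kHz
  expect_equal(a$df, 5e3)
  expect_equal(a$f_eval %% 5e3, 0)
  # windowing excludes content outside the window
  p2 <- numeric(n)
  sel1 <- t >= 10e-6 & t < 20e-6
  sel2 <- t >= 60e-6 & t < 70e-6
  p2[sel1] <- sin(2 * pi * f0 * t[sel1])
  p2[sel2] <- 10 * sin(2 * pi * f0 * t[sel2])
  tr2 <- ia_trace(t, p2)
  a_first <- amplitude_at_frequency(tr2, f0, window = c(10e-6, 20e-6))
  a_both <- amplitude_at_frequency(tr2, f0, window = c(10e-6, 70e-6))
  expect_equal(a_first$amplitude, 1, tolerance = 0.05)
  expect_gt(a_both$amplitude, 1.5)
  expect_error(amplitude_at_frequency(tr, 90e6), "Nyquist")
  expect_error(amplitude_at_frequency(tr, f0, window = c(1, 2)), "window")
})

test_that("phase shift has the stated convention and antisymmetry", {
  f0 <- 2.5e6
  n <- 2^14
  t <- (0:(n - 1)) / fs_acq
  win <- c(30e-6, 70e-6)
  ref <- ia_trace(t, sin(2 * pi * f0 * t))
  expect_equal(phase_shift(ref, ref, f0, win), 0, tolerance = 1e-6)
  # quarter-period delay -> -90 degrees
  del <- ia_trace(t, sin(2 * pi * f0 * (t - 1 / (4 * f0))))
  expect_equal(phase_shift(ref, del, f0, win), -90, tolerance = 1)
  # sign flip -> +/-180
  flip <- ia_trace(t, -sin(2 * pi * f0 * t))
  expect_equal(abs(phase_shift(ref, flip, f0, win)), 180, tolerance = 1)
  # antisymmetry mod 360
  sh <- ia_trace(t, sin(2 * pi * f0 * t - 0.7))
  p1 <- phase_shift(ref, sh, f0, win)
  p2 <- phase_shift(sh, ref, f0, win)
  expect_equal((p1 + p2 + 180) %% 360 - 180, 0, tolerance = 1e-6)
  # vanishing reference is rejected
  z <- ia_trace(t, numeric(n))
  expect_error(phase_shift(z, ref, f0, win), "phase undefined")
})

test_that("beat estimator is exact on two-impulse fixtures (+-1 bin)", {
  for (dt_sep in c(2e-6, 5e-6, 9.557e-6, 14e-6, 20e-6)) {
    for (cc in c(1400, 1556.9, 1600)) {
      tr <- two_delta_trace(dt_sep)
      br <- beat_distance(tr, c = cc)
      expect_true(br$detected)
      bin <- cc * 2 / tr$fs            # one quefrency bin in distance
      expect_lt(abs(br$peak_distance - cc * dt_sep), bin + 1e-9)
    }
  }
  # the documented worked case: 9.557 us at the tumor speed of sound
  br <- beat_distance(two_delta_trace(9.557e-6), c = 1556.9)
  expect_equal(br$peak_distance, 14.88e-3, tolerance = 1e-3)
})

test_that("single smooth pulses yield an explicit no-beat result", {
  tr <- gaussian_pulse_trace(t0 = 30e-6, sigma = 0.5e-6)
  br <- beat_distance(tr, c = 1500)
  expect_false(br$detected)
  expect_true(is.na(br$peak_distance))
})

test_that("beat truth bookkeeping reports both relative errors", {
  tr <- two_delta_trace(9.307e-6)
  br <- beat_distance(tr, c = 1556.9,
                      truth = list(distance = 14.49e-3, range = 0.114))
  expect_true(br$detected)
  expect_equal(br$rel_error_range_pct,
               abs(br$peak_distance - 14.49e-3) / 0.114 * 100)
  expect_equal(br$rel_error_distance_pct,
               abs(br$peak_distance - 14.49e-3) / 14.49e-3 * 100)
})

test_that("amplitude extraction ignores DC offsets after the detector", {
  f0 <- 2.5e6
  n <- 2^14
  t <- (0:(n - 1)) / fs_acq
  base <- sin(2 * pi * f0 * t)
  off <- base + 25
  win <- c(40e-6, 90e-6)
  a1 <- amplitude_at_frequency(detector_response(ia_trace(t, base)), f0, win)
  a2 <- amplitude_at_frequency(detector_response(ia_trace(t, off)), f0, win)
  expect_equal(a1$amplitude, a2$amplitude, tolerance = 1e-3)
})
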