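fs <- 2000
t10 <- (0:(10 * fs - 1)) / fs

test_that("band-pass preserves in-band components and rejects out-of-band", {
  x6 <- sin(2 * pi * 6 * t10)
  y <- bandpass(x6, 3, 6, fs)
  i <- 5000:15000
  gain <- sqrt(mean(y[i]^2) / mean(x6[i]^2))
  expect_gt(gain, 0.95)
  expect_lt(gain, 1.05)
  # zero-phase: no shift of the 6 Hz component
  phase_shift <- acos(sum(x6[i] * y[i]) /
                        sqrt(sum(x6[i]^2) * sum(y[i]^2))) * 180 / pi
  expect_lt(phase_shift, 1)

  x50 <- sin(2 * pi * 50 * t10)
  y50 <- bandpass(x50, 3, 6, fs)
  expect_lt(sqrt(mean(y50[i]^2)) / sqrt(mean(x50[i]^2)), 0.01)

  # one octave outside the band: > 20 dB down
  for (f0 in c(1.5, 12)) {
    y0 <- bandpass(sin(2 * pi * f0 * t10), 3, 6, fs)
    expect_lt(sqrt(mean(y0[i]^2) / 0.5), 0.1)
  }

  expect_error(bandpass(x6, 100, 1000, fs), "Nyquist")
})

test_that("filtered white noise concentrates variance in the band", {
  set.seed(11)
  y <- bandpass(rnorm(length(t10)), 140, 180, fs)
  sp <- stats::spec.pgram(stats::ts(y, frequency = fs), taper = 0,
                          plot = FALSE)
  inb <- sp$freq >= 130 & sp$freq <= 190
  expect_gt(sum(sp$spec[inb]) / sum(sp$spec), 0.9)
})

test_that("analytic phase advances at the oscillation frequency", {
  ph <- extract_phase(sin(2 * pi * 6 * t10))
  unwrapped <- cumsum(c(ph[1], atan2(sin(diff(ph)), cos(diff(ph)))))
  slope <- stats::coef(stats::lm(unwrapped ~ t10))[[2]]
  expect_lt(abs(slope - 2 * pi * 6) / (2 * pi * 6), 0.001)
})

test_that("envelope recovers amplitude and modulator", {
  a <- extract_amplitude(3 * sin(2 * pi * 150 * t10))
  i <- 500:(length(a) - 500)
  expect_lt(max(abs(a[i] - 3)) / 3, 0.01)

  # amplitude-modulated tone: envelope correlates with the modulator
  mod <- 1 + 0.5 * cos(2 * pi * 6 * t10)
  x <- mod * sin(2 * pi * 150 * t10)
  env <- trim_edges(extract_amplitude(bandpass(x, 135, 165, fs)), fs)
  expect_gt(stats::cor(env, trim_edges(mod, fs)), 0.99)
})

test_that("degenerate inputs are flagged", {
  expect_warning(ph <- extract_phase(rep(0, 1000)), "undefined")
  expect_true(all(is.na(ph)))
  expect_equal(extract_amplitude(rep(0, 1000)), rep(0, 1000))
})

test_that("edge trimming removes exactly 2 x trim_ms of samples", {
  expect_length(trim_edges(seq_len(2000), 2000), 1800)
  expect_length(trim_edges(seq_len(1000), 1000), 900)
  expect_error(trim_edges(seq_len(150), 2000), "too short")
})

test_that("phase/amplitude extraction commutes with scaling; filtering is
          time-reversal symmetric", {
  set.seed(2)
  x <- as.numeric(bandpass(rnorm(4000), 10, 30, 1000))
  expect_equal(extract_amplitude(5 * x), 5 * extract_amplitude(x),
               tolerance = 1e-12)
  expect_equal(extract_phase(5 * x), extract_phase(x), tolerance = 1e-9)
  y_fwd <- bandpass(x, 10, 30, 1000)
  y_rev <- rev(bandpass(rev(x), 10, 30, 1000))
  expect_equal(y_fwd, y_rev, tolerance = 1e-9)
})

test_that("Welch PSD satisfies Parseval and resolves a sine's power", {
  set.seed(3)
  x <- rnorm(10 * fs)
  p <- psd_welch(x, fs)
  df <- p$freq[2] - p$freq[1]
  expect_equal(sum(p$power) * df, 1, tolerance = 0.1)

  a <- 2
  p6 <- psd_welch(a * sin(2 * pi * 6 * t10), fs)
  expect_equal(band_power(p6, c(5, 10)), a^2 / 2, tolerance = 0.1 * a^2 / 2)

  p0 <- psd_welch(rep(0, 2 * fs), fs)
  expect_equal(band_power(p0, c(3, 6)), 0)
  expect_error(band_power(p6, c(900, 1100)), "outside")
})
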