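test_that("phase-amplitude distribution: uniform, concentrated, and
          raised-cosine closed forms", {
  ph <- seq(-pi, pi - 1e-9, length.out = 36000)

  P <- phase_amplitude_distribution(ph, rep(2, length(ph)))
  expect_equal(P$p, rep(1 / 18, 18), tolerance = 1e-12)

  # amplitude concentrated in one bin
  amp <- ifelse(ph >= -pi + 4 * 2 * pi / 18 & ph < -pi + 5 * 2 * pi / 18,
                1, 1e-6)
  P5 <- phase_amplitude_distribution(ph, amp)
  expect_gt(P5$p[5], 0.9)

  # amplitude = 1 + cos(phase): bin means follow the sinc-corrected
  # closed form (1 + cos(center) * sin(w/2)/(w/2)), peak at 0 degrees
  P3 <- phase_amplitude_distribution(ph, 1 + cos(ph))
  w <- 2 * pi / 18
  expected <- 1 + cos(P3$bin_centers * pi / 180) * sin(w / 2) / (w / 2)
  expect_lt(max(abs(P3$p - expected / sum(expected))), 1e-5)
  expect_equal(P3$bin_centers[which.max(P3$p)], 10)  # bin straddling 0

  expect_error(
    phase_amplitude_distribution(ph[ph > -2], rep(1, sum(ph > -2))),
    "empty phase bin")
  expect_error(phase_amplitude_distribution(1:3, 1:2), "equal length")
})

test_that("modulation index endpoints and two-bin closed form", {
  expect_equal(modulation_index(rep(1 / 18, 18)), 0, tolerance = 1e-12)
  expect_equal(modulation_index(c(1, rep(0, 17))), 1, tolerance = 1e-12)
  expect_equal(modulation_index(c(0.5, 0.5, rep(0, 16))),
               1 - log(2) / log(18), tolerance = 1e-12)
  expect_error(modulation_index(c(0.5, 0.4, rep(0, 16))), "not normalized")
  expect_error(modulation_index(c(1.5, -0.5, rep(0, 16))), "negative")
})

test_that("modulation index matches the brute-force KL oracle and is
          bounded and rotation invariant", {
  set.seed(7)
  for (k in 1:100) {
    p <- stats::rexp(18)
    p <- p / sum(p)
    expect_equal(modulation_index(p), mi_bruteforce(p), tolerance = 1e-12)
  }
  # bound over random simplex draws
  set.seed(8)
  mis <- replicate(2000, {
    p <- stats::rexp(18); modulation_index(p / sum(p))
  })
  expect_true(all(mis >= 0 & mis <= 1))
  # cyclic rotation leaves MI unchanged
  p <- stats::rexp(18); p <- p / sum(p)
  for (s in c(1, 5, 9)) {
    expect_equal(modulation_index(p), modulation_index(c(p[-(1:s)], p[1:s])),
                 tolerance = 1e-12)
  }
})

test_that("mi_for_pair is scale invariant and separates coupled from
          uncoupled signals", {
  cfg <- pac_sim_config(duration = 6, depth = 1, noise_sd = 5, seed = 21)
  x <- simulate_pac_signal(cfg)$data[, 1]
  cfg0 <- cfg; cfg0$depth <- 0
  x0 <- simulate_pac_signal(cfg0)$data[, 1]
  mi1 <- mi_for_pair(x, 2000, c(5, 7), c(135, 165))
  mi0 <- mi_for_pair(x0, 2000, c(5, 7), c(135, 165))
  expect_gt(mi1, 20 * mi0)
  expect_equal(mi_for_pair(10 * x, 2000, c(5, 7), c(135, 165)), mi1,
               tolerance = 1e-12)
  expect_error(mi_for_pair(x[1:500], 2000, c(5, 7), c(135, 165)), "1000 ms")
})

test_that("comodulogram has the standard grid shape and flags
          above-Nyquist cells", {
  set.seed(4)
  x <- rnorm(2 * 2000)
  cm <- comodulogram(x, 2000)
  expect_equal(dim(cm$mi), c(19, 33))
  expect_equal(cm$phase_freqs, 2:20)
  expect_equal(cm$amp_freqs, seq(20, 180, 5))
  # at fs = 400 the top amplitude bands exceed Nyquist and must be NA
  cm2 <- comodulogram(rnorm(2 * 400), 400, phase_freqs = c(4, 6),
                      amp_freqs = c(100, 190))
  expect_true(all(is.na(cm2$mi[, 2])))
  expect_true(all(is.finite(cm2$mi[, 1])))
})

test_that("standard distribution averages and renormalizes", {
  ph <- seq(-pi, pi - 1e-9, length.out = 36000)
  P <- phase_amplitude_distribution(ph, 1 + cos(ph))
  expect_equal(standard_distribution(list(P))$p, P$p)
  # a raised cosine and its half-turn shift average to uniform
  P2 <- phase_amplitude_distribution(ph, 1 - cos(ph))
  avg <- standard_distribution(list(P, P2))
  expect_lt(modulation_index(avg), 1e-4)
  expect_error(standard_distribution(list(P$p, rep(0.1, 10))),
               "mixed bin counts")
})

test_that("distribution correlation: identity, anti-phase, undefined", {
  ph <- seq(-pi, pi - 1e-9, length.out = 36000)
  P <- phase_amplitude_distribution(ph, 1 + cos(ph))
  Pshift <- phase_amplitude_distribution(ph, 1 - cos(ph))
  expect_equal(distribution_correlation(P, P), 1, tolerance = 1e-12)
  expect_lt(distribution_correlation(Pshift, P), -0.9)
  expect_warning(r <- distribution_correlation(rep(1 / 18, 18), P),
                 "undefined")
  expect_true(is.na(r))
})

test_that("circular-shift surrogates are seeded, flatten the mean
          distribution, and separate real coupling", {
  cfg <- pac_sim_config(duration = 8, depth = 0.9, noise_sd = 5, seed = 31)
  x <- simulate_pac_signal(cfg)$data[, 1]
  ph <- trim_edges(extract_phase(bandpass(x, 5, 7, 2000)), 2000)
  am <- trim_edges(extract_amplitude(bandpass(x, 135, 165, 2000)), 2000)
  s1 <- surrogate_mi_null(ph, am, 2000, n_surrogates = 50, seed = 9)
  s2 <- surrogate_mi_null(ph, am, 2000, n_surrogates = 50, seed = 9)
  expect_identical(s1$mi, s2$mi)
  expect_error(surrogate_mi_null(ph, am, 2000, n_surrogates = 10),
               "seed")
  # mean surrogate distribution converges toward uniform with more draws
  s20 <- surrogate_mi_null(ph, am, 2000, n_surrogates = 20, seed = 10)
  s200 <- surrogate_mi_null(ph, am, 2000, n_surrogates = 200, seed = 10)
  expect_lt(max(abs(s200$mean_p$p - 1 / 18)),
            max(abs(s20$mean_p$p - 1 / 18)))
  obs <- modulation_index(phase_amplitude_distribution(ph, am))
  expect_gt(obs, stats::quantile(s200$mi, 0.95))
})

test_that("channel selection maximizes session-averaged MI with
          deterministic tie-breaking", {
  m <- rbind(ch1 = c(0.01, 0.02), ch2 = c(0.30, 0.40), ch3 = c(0.05, 0.06))
  expect_equal(select_best_channel(m), "ch2")
  expect_equal(select_best_channel(m["ch2", , drop = FALSE]), "ch2")
  tie <- rbind(ch1 = c(0.2, 0.2), ch2 = c(0.2, 0.2))
  expect_message(best <- select_best_channel(tie), "tie")
  expect_equal(best, "ch1")
  expect_error(select_best_channel(rbind(a = c(NA, NA))), "finite")
})
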