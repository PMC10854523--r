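test_that("mean resultant vector: closed-form two-vector and symmetric
          samples", {
  mr <- mean_resultant(rep(pi / 6, 40))
  expect_equal(mr$avg_ang, pi / 6, tolerance = 1e-12)
  expect_equal(mr$r, 1, tolerance = 1e-12)

  mr2 <- mean_resultant(c(0, pi / 2))
  expect_equal(mr2$avg_ang, pi / 4, tolerance = 1e-12)
  expect_equal(mr2$r, cos(pi / 4), tolerance = 1e-12)

  mr4 <- mean_resultant(c(0, pi / 2, pi, -pi / 2))
  expect_equal(mr4$r, 0, tolerance = 1e-12)
  expect_true(is.na(mr4$avg_ang))
  expect_error(mean_resultant(numeric(0)), "at least one")
})

test_that("rotation equivariance: angles shifted by delta shift the mean
          and leave r, z, p unchanged", {
  set.seed(1)
  a <- rvm(300, mu = 0.4, kappa = 3)
  base <- mean_resultant(a)
  rt0 <- rayleigh_test(a)
  for (delta in c(0.7, -2.1, pi)) {
    shifted <- ((a + delta + pi) %% (2 * pi)) - pi
    mr <- mean_resultant(shifted)
    expect_lt(ang_diff(mr$avg_ang, base$avg_ang + delta), 1e-12)
    expect_equal(mr$r, base$r, tolerance = 1e-12)
    rt <- rayleigh_test(shifted)
    expect_equal(rt$z, rt0$z, tolerance = 1e-12)
    expect_equal(rt$p, rt0$p, tolerance = 1e-12)
  }
})

test_that("resultant length grows with von Mises concentration", {
  set.seed(2)
  rs <- vapply(c(0.5, 1, 2, 5), function(k)
    mean_resultant(rvm(1000, 0, k))$r, numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("Rayleigh test: concentrated, uniform-grid, and powered cases", {
  rt <- rayleigh_test(rep(1.2, 100))
  expect_equal(rt$z, 100, tolerance = 1e-9)
  expect_lt(rt$p, 1e-10)

  grid <- seq(-pi, pi - 2 * pi / 100, length.out = 100)
  rtg <- rayleigh_test(grid)
  expect_lt(rtg$z, 1e-10)
  expect_equal(rtg$p, 1, tolerance = 1e-6)

  set.seed(3)
  rejections <- sum(replicate(100, rayleigh_test(rvm(200, 1, 2))$p < 0.01))
  expect_gte(rejections, 99)
})

test_that("circular 95% CI: degenerate concentration, undefined for
          near-uniform samples, and nominal coverage", {
  ci <- circular_ci95(rep(0.5, 50))
  expect_lt(ci$half_width, 1e-6)

  set.seed(4)
  expect_warning(ci_u <- circular_ci95(runif(40, -pi, pi)), "undefined|dispersed")
  expect_true(is.na(ci_u$half_width))

  # coverage: n = 1000 von Mises draws, kappa = 5, 100 replicates
  set.seed(5)
  mu <- 0.9
  covered <- 0
  for (k in 1:100) {
    ci <- circular_ci95(rvm(1000, mu, 5))
    if (ang_diff(mu, ci$avg_ang) <= ci$half_width) covered <- covered + 1
  }
  expect_gte(covered, 93)
})

test_that("CI half-width shrinks with sample size at fixed concentration", {
  set.seed(6)
  hw <- vapply(c(50, 200, 1000), function(n)
    circular_ci95(rvm(n, 0, 3))$half_width, numeric(1))
  expect_true(all(diff(hw) < 0))
})

test_that("envelope peaks: constructed maxima counted, flat envelope
          yields an empty flagged sample", {
  env <- rep(1, 500)
  peaks_at <- c(50, 150, 250, 350, 450)
  env[peaks_at] <- 10
  ph <- seq(-pi, pi - 1e-9, length.out = 500)
  a <- phases_at_hf_peaks(ph, env)
  expect_length(a, 5)
  expect_equal(attr(a, "peak_index"), peaks_at)
  expect_equal(a, ph[peaks_at], ignore_attr = TRUE)

  expect_message(empty <- phases_at_hf_peaks(ph, rep(1, 500)), "no supra")
  expect_length(empty, 0)
})

test_that("phases at envelope peaks recover the injected preferred phase", {
  cfg <- pac_sim_config(duration = 20, depth = 0.9, noise_sd = 5,
                        preferred_phase = pi / 3, seed = 17)
  x <- simulate_pac_signal(cfg)$data[, 1]
  ph <- trim_edges(extract_phase(bandpass(x, 5, 7, 2000)), 2000)
  am <- trim_edges(extract_amplitude(bandpass(x, 135, 165, 2000)), 2000)
  a <- phases_at_hf_peaks(ph, am)
  expect_gte(length(a), 5)
  mr <- mean_resultant(a)
  expect_lt(ang_diff(mr$avg_ang, pi / 3), 15 * pi / 180)
})
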