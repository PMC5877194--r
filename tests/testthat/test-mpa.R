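test_that("the noiseless Markov amplitude decays geometrically", {
  a <- markov_amplitude(0.5, 0, 5, a0 = 5)
  expect_equal(a, 5 * 0.5^(0:4))
  expect_error(markov_amplitude(1, 1, 10), "strictly in \\(0, 1\\)")
  expect_error(markov_amplitude(0, 1, 10), "strictly in \\(0, 1\\)")
})

test_that("Markov amplitudes reach the AR(1) stationary variance", {
  pars <- list(c(0.99, 2.26), c(0.97, 2.78), c(0.99, 2.35), c(0.99, 0.36))
  for (i in seq_along(pars)) {
    g <- pars[[i]][1]; s <- pars[[i]][2]
    a <- markov_amplitude(g, s, 2e5, seed = 1000 + i)
    expect_equal(stats::var(a), s^2 / (1 - g^2), tolerance = 0.1)
  }
})

test_that("seeded generation is reproducible and leaves the RNG alone", {
  a1 <- markov_amplitude(0.9, 1, 100, seed = 7)
  a2 <- markov_amplitude(0.9, 1, 100, seed = 7)
  expect_identical(a1, a2)
  withr::with_seed(1, {
    before <- rnorm(1)
    set.seed(1)
    invisible(markov_amplitude(0.9, 1, 10, seed = 3))
    expect_identical(rnorm(1), before)
  })
})

test_that("a rhythm is the amplitude-modulated sinusoid", {
  p <- rhythm_params("test", f = 10, gamma = 0.5, sigma_xi = 0)
  x <- simulate_rhythm(p, fs = 200, duration = 1, a0 = 1)
  t <- (0:199) / 200
  expect_equal(x$value_uV, 0.5^(0:199) * sin(2 * pi * 10 * t))

  # doubling a0 doubles the RMS in the noiseless case
  x2 <- simulate_rhythm(p, fs = 200, duration = 1, a0 = 2)
  expect_equal(sqrt(mean(x2$value_uV^2)), 2 * sqrt(mean(x$value_uV^2)))
})

test_that("each simulated rhythm peaks at its nominal frequency", {
  for (r in mpa_rhythms()) {
    x <- simulate_rhythm(r, fs = 200, duration = 8, seed = 11)
    psd <- estimate_psd(x)
    expect_lte(abs(psd$frequency_hz[which.max(psd$power)] - r$f), 0.5)
  }
})

test_that("the spontaneous EEG is the superposition of its four rhythms", {
  sim <- simulate_eeg(mpa_config("spontaneous", seed = 9))
  expect_equal(sim$spontaneous, sim$delta + sim$theta + sim$alpha + sim$beta)
  expect_equal(sim$eeg, sim$spontaneous) # no artifacts, no noise
  expect_true(all(sim$eog == 0) && all(sim$noise == 0))
})

test_that("rhythm order does not change the simulated record", {
  cfg1 <- mpa_config("spontaneous", seed = 5)
  cfg2 <- mpa_config("spontaneous", seed = 5, rhythms = rev(mpa_rhythms()))
  expect_equal(simulate_eeg(cfg1)$eeg, simulate_eeg(cfg2)$eeg)
})

test_that("EOG pulses have exact peak, spacing and quiet baseline", {
  e <- eog_waveform(artifact_params(), fs = 200, duration = 8)
  v <- e$value_uV
  expect_equal(max(v), 50)
  expect_equal(sum(v == 50), 3) # apexes at 1.5, 4.5, 7.5 s
  expect_equal(v[e$time == 3.0], 0) # midway between pulses
  expect_equal(mean(v > 0), 0.3 / 3, tolerance = 0.15) # ~10% duty cycle
})

test_that("baseline drift is the configured slow sinusoid", {
  d <- baseline_drift(artifact_params(), fs = 200, duration = 8)
  expect_equal(max(abs(d$value_uV)), 10) # amplitude reached exactly at t = 0.5
  expect_equal(d$value_uV[1], 0)
  # period 2 s: 4 complete cycles in 8 s
  expect_equal(d$value_uV[d$time >= 2], d$value_uV[d$time < 6], tolerance = 1e-12)
})

test_that("white noise variance follows the decibel setting", {
  w1 <- white_noise(1, fs = 200, duration = 500, seed = 3)
  expect_equal(stats::var(w1$value_uV), 10^0.1, tolerance = 0.05)
  w0 <- white_noise(0, fs = 200, duration = 500, seed = 4)
  expect_equal(stats::var(w0$value_uV), 1, tolerance = 0.05)
  expect_identical(
    white_noise(1, 200, 1, seed = 5)$value_uV,
    white_noise(1, 200, 1, seed = 5)$value_uV
  )
})

test_that("the full record adds artifacts and noise to the spontaneous EEG", {
  sim <- simulate_eeg(mpa_config("full", seed = 12))
  expect_equal(sim$eeg, sim$spontaneous + sim$eog + sim$drift + sim$noise)
  # artifact peaks dwarf the typical spontaneous excursion
  expect_gt(max(abs(sim$eog + sim$drift)), 2 * sqrt(mean(sim$spontaneous^2)))
})

test_that("eyes-open preset attenuates exactly the alpha stream", {
  closed <- simulate_eeg(mpa_config("eyes-closed", seed = 21))
  open <- simulate_eeg(mpa_config("eyes-open", seed = 21))
  expect_equal(open$alpha, 0.3 * closed$alpha) # same seeded innovations, scaled
  expect_equal(open$delta, closed$delta)
  expect_lt(
    band_power(estimate_psd(sim_channel(open, "eeg")), rhythm_band("alpha")),
    band_power(estimate_psd(sim_channel(closed, "eeg")), rhythm_band("alpha"))
  )
})

test_that("configuration validation catches unusable setups", {
  expect_error(mpa_config("full", fs = 40), "twice the fastest")
  expect_error(artifact_params(w_eog = 3, t_eog = 3), "smaller than")
  expect_error(artifact_params(v_eog = -1), "non-negative")
  expect_error(rhythm_params("x", f = 10, gamma = 1.2, sigma_xi = 1), "strictly in")
})
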