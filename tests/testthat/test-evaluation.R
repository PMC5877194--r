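test_that("the Welch PSD localises a sinusoid and scales as a density", {
  psd <- estimate_psd(make_sinusoid(10.5, fs = 200, n = 1600))
  expect_lte(abs(psd$frequency_hz[which.max(psd$power)] - 10.5), 0.5)
  expect_true(all(psd$power >= 0))
  expect_equal(range(psd$frequency_hz), c(0, 100))
  expect_equal(attr(psd, "segment_length"), 400L)
  expect_equal(attr(psd, "window"), "hann")
})

test_that("the PSD integrates to the signal power (Parseval)", {
  for (x in list(make_noise(n = 2000, seed = 6),
                 make_sinusoid(10.5, n = 1600, amp = 3))) {
    psd <- estimate_psd(x)
    df <- diff(psd$frequency_hz[1:2])
    expect_equal(sum(psd$power) * df, mean(x$value_uV^2), tolerance = 0.1)
  }
})

test_that("PSD handles degenerate inputs", {
  psd0 <- estimate_psd(rep(0, 200), fs = 100)
  expect_true(all(psd0$power == 0))
  expect_error(estimate_psd(rnorm(32), fs = 100), "N >= 64")
})

test_that("eps_ave is the mean absolute bin difference on a shared grid", {
  grid <- tibble::tibble(frequency_hz = c(0, 1, 2))
  pa <- dplyr::mutate(grid, power = c(1, 2, 3))
  pr <- dplyr::mutate(grid, power = c(2, 2, 1))
  expect_equal(eps_ave(pa, pr), 1.0) # mean of |1 - 2|, |2 - 2|, |3 - 1|
  expect_equal(eps_ave(pa, pa), 0)
  expect_equal(eps_ave(pa, pr), eps_ave(pr, pa)) # symmetric
  bad <- tibble::tibble(frequency_hz = c(0, 1.5, 2), power = 1:3)
  expect_error(eps_ave(pa, bad), "grids differ")
})

test_that("rhythm power is the mean square with its closed forms", {
  expect_equal(rhythm_power(rep(3, 10)), 9)
  expect_equal(rhythm_power(rep(0, 10)), 0)
  # amplitude A over an integer number of cycles -> A^2 / 2
  x <- make_sinusoid(10, fs = 200, n = 1600, amp = 2.5)
  expect_equal(rhythm_power(x), 2.5^2 / 2, tolerance = 1e-6)
  # order-invariant and quadratic in scale
  withr::with_seed(3, v <- rnorm(50))
  expect_equal(rhythm_power(sample(v)), rhythm_power(v))
  expect_equal(rhythm_power(3 * v), 9 * rhythm_power(v))
})

test_that("threshold classification follows the power rule", {
  out <- classify_by_threshold(data.frame(power_uV2 = c(5, 20)), 12)
  expect_equal(out$predicted_state, c("eyes-open", "eyes-closed"))
  all_closed <- classify_by_threshold(data.frame(power_uV2 = c(1, 2, 3)), 0)
  expect_true(all(all_closed$predicted_state == "eyes-closed"))
  expect_error(classify_by_threshold(data.frame(x = 1), 1), "power_uV2")
  expect_error(classify_by_threshold(data.frame(power_uV2 = 1), -1), "non-negative")
})

test_that("accuracy counts matches and rejects degenerate input", {
  expect_equal(classification_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(classification_accuracy(c("a", "b"), c("a", "a")), 0.5)
  expect_equal(classification_accuracy(c("b", "a"), c("a", "b")), 0)
  expect_error(classification_accuracy("a", c("a", "b")), "equal length")
  expect_error(classification_accuracy(character(0), character(0)), "Empty")
})

test_that("the threshold sweep finds a separating threshold when one exists", {
  f <- data.frame(
    power_uV2 = c(1, 2, 3, 10, 11, 12),
    true_state = rep(c("eyes-open", "eyes-closed"), each = 3)
  )
  sw <- sweep_threshold(f)
  expect_equal(sw$best_accuracy, 1)
  expect_gt(sw$best_threshold, 3)
  expect_lt(sw$best_threshold, 10)
  expect_true(all(sw$sweep$accuracy <= 1 & sw$sweep$accuracy >= 0))
})

test_that("the IIR baseline passes the band and rejects out-of-band tones", {
  band <- rhythm_band("alpha")
  inband <- iir_bandpass(make_sinusoid(10.5, n = 1600), band)
  expect_equal(
    sqrt(mean(inband$value_uV^2)), sqrt(0.5), tolerance = 0.05
  )
  low <- iir_bandpass(make_sinusoid(2.5, n = 1600), band)
  expect_lt(sqrt(mean(low$value_uV^2)), 0.1 * sqrt(0.5))
  z <- iir_bandpass(eeg_signal(rep(0, 400), fs = 200), band)
  expect_true(all(abs(z$value_uV) < 1e-12))
  expect_error(
    iir_bandpass(make_sinusoid(10, fs = 20, n = 100), band), "Nyquist"
  )
})
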