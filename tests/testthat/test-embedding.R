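test_that("the L = fs/fb rule rounds up and bounds the component bandwidth", {
  L <- select_embedding(200, 5)
  expect_identical(as.integer(L), 40L)
  expect_equal(attr(L, "component_bandwidth_hz"), 5)
  expect_identical(as.integer(select_embedding(200, 2.5)), 80L)
  expect_identical(as.integer(select_embedding(250, 4)), 63L) # ceiling(62.5)

  expect_error(select_embedding(200, 150), "not resolvable")
  expect_error(select_embedding(200, 0), "positive")
  expect_error(select_embedding(-1, 5), "positive")
})

test_that("component bandwidth is exactly fs/L", {
  expect_equal(component_bandwidth(200, 20), 10)
  expect_equal(component_bandwidth(200, 40), 5)
  expect_equal(component_bandwidth(200, 80), 2.5)
  expect_error(component_bandwidth(200, 0), "positive integer")
})

test_that("the selection rule always achieves the requested bandwidth", {
  withr::with_seed(17, {
    for (i in 1:50) {
      fs <- runif(1, 50, 1000)
      fb <- runif(1, 0.5, fs / 2)
      expect_lte(component_bandwidth(fs, select_embedding(fs, fb)), fb)
    }
  })
})

test_that("Toeplitz lags sum exactly K products and approximate X'X", {
  tc <- suppressWarnings(toeplitz_covariance(rep(1, 5), L = 2)) # K = 4 is short
  expect_equal(tc$lags, c(4, 4)) # K = 4 products of ones
  expect_equal(tc$matrix, matrix(4, 2, 2))

  x <- make_noise(n = 1600, seed = 21)
  tc <- toeplitz_covariance(x, L = 40)
  X <- ssa_embed(x, 40)
  ctc <- crossprod(X)
  expect_lt(norm(ctc - tc$matrix, "F") / norm(ctc, "F"), 0.05)
})

test_that("short records trigger the Toeplitz approximation warning", {
  expect_warning(toeplitz_covariance(make_noise(n = 100), L = 20), "K = ")
  expect_no_warning(toeplitz_covariance(make_noise(n = 1600), L = 40))
})

test_that("circulant eigenvalue formula tracks the true Toeplitz spectrum", {
  tc <- toeplitz_covariance(make_noise(n = 1600, seed = 5), L = 40)
  circ <- sort(toeplitz_circulant_eigenvalues(tc), decreasing = TRUE)
  true <- sort(eigen(tc$matrix, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
  half <- seq_len(20)
  expect_lt(mean(abs(circ[half] - true[half]) / true[half]), 0.10)
})

test_that("the DFT kernel has its exact peak value at integer alignment", {
  for (L in c(5, 20, 37)) {
    sa <- spectral_approximation(make_noise(n = 400, seed = L), L = L)
    expect_equal(sa$zeta[1, 1], 2 * L - 1) # p = q = 0
    # zeta = 2L - 1 wherever p/L + q/K is an integer
    k <- sa$K
    for (p in 0:(L - 1)) {
      q_int <- which(((0:(k - 1)) / k + p / L) %% 1 < 1e-12)
      if (length(q_int)) {
        expect_true(all(abs(sa$zeta[p + 1, q_int] - (2 * L - 1)) < 1e-8))
      }
    }
  }
})

test_that("approximate eigenvalues vanish for a zero signal", {
  sa <- spectral_approximation(rep(0, 200), L = 20)
  expect_equal(sa$approx_eigenvalues, rep(0, 20))
})

test_that("a sinusoid's dominant approximate eigenvalue sits in the right slice", {
  sa <- spectral_approximation(make_sinusoid(10.5, fs = 200, n = 1600), L = 40)
  p_star <- which.max(sa$approx_eigenvalues) - 1L
  centre <- p_star * 200 / 40 # slice centre frequency, width fs/L = 5 Hz
  expect_lte(abs(centre - 10.5), 2.5)
})

test_that("approximate eigenvalues agree with the Toeplitz spectrum on broadband signals", {
  errs <- vapply(1:5, function(seed) {
    x <- make_noise(n = 1600, seed = 100 + seed)
    sa <- spectral_approximation(x, L = 40)
    tc <- toeplitz_covariance(x, L = 40)
    true <- sort(eigen(tc$matrix, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
    appr <- sort(sa$approx_eigenvalues, decreasing = TRUE)
    half <- seq_len(20)
    mean(abs(appr[half] - true[half]) / true[half])
  }, numeric(1))
  expect_lt(max(errs), 0.15)
})

test_that("the eigenvalue approximation improves with record length", {
  err_at <- function(n) {
    x <- make_noise(n = n, seed = 7)
    sa <- spectral_approximation(x, L = 40)
    tc <- suppressWarnings(toeplitz_covariance(x, L = 40))
    true <- sort(eigen(tc$matrix, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
    appr <- sort(sa$approx_eigenvalues, decreasing = TRUE)
    half <- seq_len(20)
    mean(abs(appr[half] - true[half]) / true[half])
  }
  errs <- vapply(c(400, 1600, 6400), err_at, numeric(1))
  expect_lt(errs[3], errs[1])
})

test_that("trace deltas equal the sample-sum identity exactly", {
  s <- make_noise(n = 1600, seed = 31)$value_uV
  Ls <- seq(10, 100, by = 10)
  tp <- trace_profile(s, Ls)
  eq_rhs <- vapply(Ls, function(L) sum(s[L:(1600 - L + 1)]^2), numeric(1))
  expect_equal(tp$delta, eq_rhs, tolerance = 1e-12)
  # change rate shrinks as L grows
  expect_lt(unname(stats::coef(stats::lm(tp$delta ~ tp$L))[2]), 0)
})

test_that("trace profile handles zero input and unsorted L", {
  tp0 <- trace_profile(rep(0, 100), c(5, 10))
  expect_equal(tp0$trace, c(0, 0))
  tp <- trace_profile(make_noise(n = 200)$value_uV, c(30, 10, 20))
  expect_equal(tp$L, c(10L, 20L, 30L))
  expect_error(trace_profile(make_noise(n = 100)$value_uV, c(2, 100)), "\\[2, 99\\]")
})

test_that("the recommendation report carries the rule and its caveats", {
  x <- simulate_spontaneous(mpa_config("spontaneous", seed = 2))
  rep1 <- recommend_embedding(x, rhythm_band("alpha"))
  expect_equal(rep1$L, 40L)
  expect_equal(rep1$component_bandwidth_hz, 5)
  expect_length(rep1$warnings, 0)
  expect_s3_class(rep1$trace_profile, "tbl_df")

  # record too short for the requested bandwidth: fs/fb > N/2
  short <- make_noise(n = 70, fs = 200)
  rep2 <- recommend_embedding(short, rhythm_band("alpha"))
  expect_true(any(grepl("N/2", rep2$warnings)))

  flat <- eeg_signal(rep(1, 400), fs = 200)
  rep3 <- recommend_embedding(flat, rhythm_band("alpha"))
  expect_true(rep3$degenerate)
})
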