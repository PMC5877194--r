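#' Select the SSA embedding dimension from the rhythm bandwidth
#'
#' The central design rule of the package: each reconstructed component of an
#' SSA decomposition with window length L has its spectrum confined to a band
#' of width about fs/L. To extract a rhythm of bandwidth `fb` without either
#' letting out-of-band energy in (L too small) or splitting/mixing the rhythm
#' across components (L too large), choose the smallest L whose component
#' bandwidth does not exceed fb:
#'
#'   L = ceiling(fs / fb)
#'
#' The ceiling guarantees fs/L <= fb for non-divisible ratios.
#'
#' @param fs Sampling rate (Hz).
#' @param fb Bandwidth of the rhythm of interest (Hz); must satisfy
#'   0 < fb <= fs/2, otherwise the band is not resolvable at this rate.
#' @return Integer L, with attribute `component_bandwidth_hz` = fs/L.
#' @examples
#' select_embedding(200, 5) # alpha band (8-13 Hz) at 200 Hz -> 40
#' @export
select_embedding <- function(fs, fb) {
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    rlang::abort("`fs` must be a single positive number (Hz).")
  }
  if (!is.numeric(fb) || length(fb) != 1 || !is.finite(fb) || fb <= 0) {
    rlang::abort("`fb` must be a single positive number (Hz).")
  }
  if (fb > fs / 2) {
    rlang::abort(sprintf(
      "Bandwidth fb = %g Hz is not resolvable at fs = %g Hz (requires fb <= fs/2).",
      fb, fs
    ))
  }
  L <- as.integer(ceiling(fs / fb))
  attr(L, "component_bandwidth_hz") <- fs / L
  L
}

#' Component bandwidth implied by an embedding dimension
#'
#' The spectral width of each reconstructed component: fs/L. Equal to the DFT
#' resolution fs/K times the number K/L of spectral bins each eigenvalue of
#' the lag-covariance matrix averages over.
#'
#' @inheritParams select_embedding
#' @param L Embedding dimension (>= 1).
#' @return Bandwidth in Hz (exactly fs/L).
#' @examples
#' component_bandwidth(200, 40) # 5 Hz
#' @export
component_bandwidth <- function(fs, L) {
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    rlang::abort("`fs` must be a single positive number (Hz).")
  }
  if (!is.numeric(L) || length(L) != 1 || !is.finite(L) || L < 1 || L != round(L)) {
    rlang::abort("`L` must be a single positive integer.")
  }
  fs / L
}

#' Toeplitz approximation of the SSA lag-covariance matrix
#'
#' When K = N - L + 1 >> L, the entries of X'X along each diagonal are nearly
#' equal and X'X is well approximated by the symmetric Toeplitz matrix built
#' from the lagged sums
#'
#'   z_l = sum_{n=1}^{K} s_n s_{n+l},  l = 0, ..., L-1,
#'
#' each a sum of exactly K products (the needed samples up to index
#' K + L - 1 = N exist by construction). The approximation quality degrades
#' for short series; a warning is issued when K < 10 L.
#'
#' @inheritParams ssa_embed
#' @return An object of class `toeplitz_cov`: list with `lags` (z_0..z_{L-1}),
#'   `matrix` (L x L symmetric Toeplitz), `L`, `K`, `n`.
#' @export
toeplitz_covariance <- function(x, L) {
  s <- signal_values(x)
  n <- length(s)
  L <- check_embedding_dim(L, n)
  k <- n - L + 1L
  if (k < 10L * L) {
    rlang::warn(sprintf(
      "K = %d < 10 L = %d: the Toeplitz approximation of X'X may be poor.",
      k, 10L * L
    ))
  }
  z <- vapply(0:(L - 1L), function(l) {
    sum(s[1:k] * s[(1 + l):(k + l)])
  }, numeric(1))
  structure(
    list(lags = z, matrix = stats::toeplitz(z), L = L, K = k, n = n),
    class = "toeplitz_cov"
  )
}

#' @export
print.toeplitz_cov <- function(x, ...) {
  cat(sprintf(
    "<toeplitz_cov> %d x %d symmetric Toeplitz (K = %d lagged products per entry)\n",
    x$L, x$L, x$K
  ))
  cat("z_0 =", format(x$lags[1]), "\n")
  invisible(x)
}

#' Circulant (Fourier) approximation to the Toeplitz eigenvalues
#'
#' Treating the Toeplitz lag-covariance matrix as circulant gives the
#' closed-form eigenvalue approximation
#'
#'   lambda_p = z_0 + 2 sum_{j=1}^{L-1} z_j cos(2 pi j p / L),  p = 0..L-1.
#'
#' Useful as a diagnostic; exact only in the circulant limit.
#'
#' @param tc A `toeplitz_cov` object.
#' @return Numeric vector of length L (p = 0..L-1).
#' @export
toeplitz_circulant_eigenvalues <- function(tc) {
  stopifnot(inherits(tc, "toeplitz_cov"))
  L <- tc$L
  z <- tc$lags
  p <- 0:(L - 1L)
  j <- seq_len(L - 1L)
  vapply(p, function(pp) {
    tc$lags[1] + 2 * sum(z[j + 1L] * cos(2 * pi * j * pp / L))
  }, numeric(1))
}

#' DFT-based approximation of the lag-covariance eigenvalue spectrum
#'
#' Expresses each eigenvalue of the Toeplitz lag-covariance matrix as a
#' weighted sum of the signal's DFT power:
#'
#'   lambda_p = sum_{q=0}^{K-1} |s_hat_q|^2 zeta_{p,q},
#'   zeta_{p,q} = 1 + 2 sum_{m=1}^{L-1} cos(2 pi m (p/L + q/K)),
#'
#' where s_hat is the unitary DFT of the first K samples. The kernel
#' zeta_{p,q} is a Dirichlet window of width about K/L bins centred where
#' p/L + q/K is an integer (there zeta = 2L - 1), so each eigenvalue averages
#' a spectral slice of width roughly fs/L — the argument behind the
#' L = fs/fb selection rule. This is a diagnostic; rhythm extraction always
#' uses the actual SVD.
#'
#' @inheritParams ssa_embed
#' @return An object of class `spectral_approx`: list with `power`
#'   (|s_hat_q|^2, length K), `zeta` (L x K kernel matrix),
#'   `approx_eigenvalues` (length L, p = 0..L-1), `L`, `K`, `n`.
#' @export
spectral_approximation <- function(x, L) {
  s <- signal_values(x)
  n <- length(s)
  L <- check_embedding_dim(L, n)
  k <- n - L + 1L
  sk <- s[1:k]
  power <- Mod(stats::fft(sk))^2 / k # unitary DFT normalisation
  q <- 0:(k - 1L)
  zeta <- matrix(0, nrow = L, ncol = k)
  for (p in 0:(L - 1L)) {
    zeta[p + 1L, ] <- dirichlet_kernel(p / L + q / k, L)
  }
  structure(
    list(
      power = power,
      zeta = zeta,
      approx_eigenvalues = as.vector(zeta %*% power),
      L = L, K = k, n = n
    ),
    class = "spectral_approx"
  )
}

# 1 + 2 sum_{m=1}^{L-1} cos(2 pi m u) via the closed Dirichlet form,
# with the removable singularity at integer u handled exactly (value 2L - 1).
dirichlet_kernel <- function(u, L) {
  frac <- u - round(u)
  out <- numeric(length(u))
  at_peak <- abs(frac) < 1e-12
  out[at_peak] <- 2 * L - 1
  uu <- frac[!at_peak]
  out[!at_peak] <- sin((2 * L - 1) * pi * uu) / sin(pi * uu)
  out
}

#' @export
print.spectral_approx <- function(x, ...) {
  cat(sprintf(
    "<spectral_approx> L = %d eigenvalue estimates from a K = %d point DFT\n",
    x$L, x$K
  ))
  invisible(x)
}

#' Trace profile of the lag covariance across embedding dimensions
#'
#' The trace of the lag-covariance matrix X'X equals the squared Frobenius
#' norm of the trajectory matrix, i.e. each sample s_j^2 weighted by the
#' number of windows covering it: Tr_L = sum_j min(j, L, K, N - j + 1) s_j^2.
#' Consecutive differences obey the exact identity
#'
#'   Tr_L - Tr_{L-1} = sum_{j=L}^{K} s_j^2,  K = N - L + 1,
#'
#' so the trace gain shrinks as L grows: the information added per unit of
#' window length decays, which is the second argument for preferring the
#' smallest L compatible with the target bandwidth.
#'
#' @inheritParams ssa_embed
#' @param L_values Integer vector of embedding dimensions (sorted internally;
#'   duplicates dropped).
#' @return A tibble with columns `L`, `K`, `trace`, `delta`
#'   (= Tr_L - Tr_{L-1}, the trace change rate at unit step).
#' @export
trace_profile <- function(x, L_values) {
  s <- signal_values(x)
  n <- length(s)
  Ls <- sort(unique(as.integer(L_values)))
  if (any(Ls < 2L) || any(Ls > n - 1L)) {
    rlang::abort(sprintf("All L values must lie in [2, %d].", n - 1L))
  }
  tr_at <- function(L) {
    if (L < 1L) return(0)
    j <- seq_len(n)
    sum(pmin(j, L, n - L + 1L, n - j + 1L) * s[j]^2)
  }
  traces <- vapply(Ls, tr_at, numeric(1))
  deltas <- traces - vapply(Ls - 1L, tr_at, numeric(1))
  tibble::tibble(L = Ls, K = n - Ls + 1L, trace = traces, delta = deltas)
}

#' Embedding-dimension recommendation report
#'
#' Bundles the selection rule with its diagnostics: the chosen L for the
#' requested band, the implied component bandwidth, a trace profile around the
#' chosen L, and explicit warnings when the rule collides with the record
#' length (L may never exceed K = N - L + 1; the most detailed decomposition
#' possible is at L about N/2).
#'
#' @inheritParams ssa_embed
#' @param band A [rhythm_band()].
#' @param fs Sampling rate in Hz; taken from `x` when omitted.
#' @return An object of class `embedding_report`.
#' @export
recommend_embedding <- function(x, band, fs = NULL) {
  stopifnot(inherits(band, "rhythm_band"))
  fs <- signal_fs(x, fs)
  s <- signal_values(x)
  n <- length(s)
  L <- as.integer(select_embedding(fs, band$fb))
  warnings <- character()
  if (fs / band$fb > n / 2) {
    warnings <- c(warnings, sprintf(
      "fs/fb = %.1f exceeds N/2 = %.1f: the record is too short to resolve this band; decomposition detail is capped near L = N/2.",
      fs / band$fb, n / 2
    ))
  }
  if (L > n - L + 1L) {
    warnings <- c(warnings, sprintf(
      "Chosen L = %d exceeds K = %d lagged vectors; reduce L or record longer data.",
      L, n - L + 1L
    ))
  }
  degenerate <- stats::sd(s) == 0
  if (degenerate) {
    warnings <- c(warnings, "Input series is constant (rank-1 trajectory matrix); any L is degenerate.")
  }
  grid <- unique(pmin(pmax(2L, round(seq(max(2, L / 4), min(2 * L, n - 1), length.out = 9))), n - 1L))
  profile <- if (degenerate || L > n - 1L) NULL else trace_profile(s, grid)
  structure(
    list(
      band = band, fs = fs, n = n,
      L = min(L, n - 1L),
      rule_L = L,
      component_bandwidth_hz = fs / L,
      trace_profile = profile,
      warnings = warnings,
      degenerate = degenerate
    ),
    class = "embedding_report"
  )
}

#' @export
print.embedding_report <- function(x, ...) {
  cat(sprintf(
    "<embedding_report> band %s [%g, %g] Hz (fb = %g Hz) at fs = %g Hz\n",
    x$band$name, x$band$f_low, x$band$f_high, x$band$fb, x$fs
  ))
  cat(sprintf(
    "  recommended L = %d  (component bandwidth fs/L = %g Hz; N = %d, K = %d)\n",
    x$L, x$component_bandwidth_hz, x$n, x$n - x$L + 1L
  ))
  if (x$degenerate) cat("  input flagged degenerate (constant series)\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
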