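#' Time-delay embedding: build the trajectory matrix
#'
#' Maps a length-N series into the K x L Hankel trajectory matrix whose row k
#' is the lagged window (s_k, ..., s_{k+L-1}), with K = N - L + 1 lagged
#' vectors. Constant anti-diagonals (Hankel structure) are what diagonal
#' averaging later exploits.
#'
#' @inheritParams signal_fs
#' @param L Embedding dimension (window length), 2 <= L <= N - 1.
#' @return A K x L numeric matrix with attributes `L`, `K` and `n`.
#' @examples
#' ssa_embed(c(1, 2, 3, 4), L = 2)
#' @export
ssa_embed <- function(x, L) {
  s <- signal_values(x)
  n <- length(s)
  L <- check_embedding_dim(L, n)
  k <- n - L + 1L
  X <- matrix(0, nrow = k, ncol = L)
  for (j in seq_len(L)) {
    X[, j] <- s[j:(j + k - 1L)]
  }
  structure(X, L = L, K = k, n = n)
}

check_embedding_dim <- function(L, n) {
  if (!is.numeric(L) || length(L) != 1 || !is.finite(L) || L != round(L)) {
    rlang::abort("`L` must be a single integer.")
  }
  L <- as.integer(L)
  if (L < 2L || L > n - 1L) {
    rlang::abort(sprintf(
      "Embedding dimension L = %d out of range: valid interval is [2, %d] for N = %d.",
      L, n - 1L, n
    ))
  }
  L
}

#' Diagonal averaging (Hankelization) of a matrix
#'
#' Maps a K x L matrix back to a length K + L - 1 series: each output sample
#' is the mean of the anti-diagonal entries m[k, l] with k + l - 1 = t. For a
#' Hankel matrix this inverts the embedding exactly.
#'
#' @param m Numeric matrix.
#' @return Numeric vector of length `nrow(m) + ncol(m) - 1`.
#' @examples
#' diagonal_average(matrix(c(1, 3, 2, 4), 2)) # (1, (2 + 3)/2, 4)
#' @export
diagonal_average <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) {
    rlang::abort("`m` must be a numeric matrix.")
  }
  idx <- as.vector(row(m) + col(m) - 1L)
  sums <- rowsum(as.vector(m), idx)
  as.vector(sums) / antidiag_counts(nrow(m), ncol(m))
}

# number of entries on each anti-diagonal of a K x L matrix
antidiag_counts <- function(k, l) {
  t <- seq_len(k + l - 1L)
  pmin(t, k, l, k + l - t)
}

# Diagonal average of the rank-one matrix d * u v^T without forming it:
# the anti-diagonal sums of u v^T are the linear convolution of u and v.
rank1_diagonal_average <- function(d, u, v) {
  conv <- stats::convolve(u, rev(v), type = "open")
  d * conv / antidiag_counts(length(u), length(v))
}

#' Singular spectrum analysis of a single-channel signal
#'
#' Runs the decomposition stage of SSA: time-delay embedding into the K x L
#' trajectory matrix followed by singular value decomposition. Eigenvalues are
#' reported as squared singular values of the trajectory matrix (the
#' eigenvalues of the lag-covariance matrix X'X), sorted non-increasing.
#' Singular values below `max(K, L) * eps * sigma_1` are treated as numerical
#' zeros and dropped, so the rank r satisfies lambda_r > 0. Each retained
#' elementary matrix sqrt(lambda_i) u_i v_i' is diagonal-averaged into a
#' reconstructed component (RC) series of length N; by linearity the r RCs sum
#' to the input exactly (up to round-off).
#'
#' The SVD is taken of the trajectory matrix directly rather than by
#' eigen-decomposing X'X, which squares the condition number.
#'
#' @inheritParams ssa_embed
#' @param fs Sampling rate in Hz; taken from `x` when omitted.
#' @return An object of class `eeg_ssa`: a list with elements `eigenvalues`,
#'   `singular_values`, `u` (K x r), `v` (L x r), `rank`, `components`
#'   (N x r matrix of RC series), `series`, `n`, `L`, `K`, `fs`.
#' @examples
#' x <- eeg_signal(sin(2 * pi * 10.5 * (0:799) / 200), fs = 200)
#' fit <- ssa(x, L = 40)
#' fit
#' generics::tidy(fit)
#' @export
ssa <- function(x, L, fs = NULL) {
  fs <- signal_fs(x, fs)
  s <- signal_values(x)
  X <- ssa_embed(s, L)
  if (!all(is.finite(X))) {
    rlang::abort("Trajectory matrix contains non-finite entries.")
  }
  k <- attr(X, "K")
  L <- attr(X, "L")
  sv <- svd(X)
  d <- sv$d
  tol <- max(k, L) * .Machine$double.eps * max(d, 0)
  r <- sum(d > tol)
  n <- length(s)
  comp <- matrix(0, nrow = n, ncol = r)
  for (i in seq_len(r)) {
    comp[, i] <- rank1_diagonal_average(d[i], sv$u[, i], sv$v[, i])
  }
  structure(
    list(
      eigenvalues = d[seq_len(r)]^2,
      singular_values = d[seq_len(r)],
      u = sv$u[, seq_len(r), drop = FALSE],
      v = sv$v[, seq_len(r), drop = FALSE],
      rank = r,
      components = comp,
      series = s,
      n = n,
      L = L,
      K = k,
      fs = fs
    ),
    class = "eeg_ssa"
  )
}

#' @export
print.eeg_ssa <- function(x, ...) {
  cat(sprintf(
    "<eeg_ssa> N = %d samples at %g Hz, L = %d (K = %d), rank r = %d\n",
    x$n, x$fs, x$L, x$K, x$rank
  ))
  if (x$rank > 0) {
    share <- x$eigenvalues / sum(x$eigenvalues)
    top <- utils::head(share, 5)
    cat(
      "leading eigenvalue shares:",
      paste(sprintf("%.3f", top), collapse = " "), "\n"
    )
  }
  invisible(x)
}

#' Reconstruct a grouped subset of SSA components
#'
#' Sums the chosen elementary matrices and diagonal-averages the result into a
#' single series (equivalently, sums the individual RC series: diagonal
#' averaging is linear). This is the grouping + reconstruction stage of SSA.
#'
#' @param object An `eeg_ssa` fit.
#' @param components Integer vector of 1-based RC indices (non-empty, unique,
#'   each in 1..rank).
#' @return An [eeg_signal()] tibble of length N.
#' @export
ssa_reconstruct <- function(object, components) {
  stopifnot(inherits(object, "eeg_ssa"))
  if (length(components) == 0) {
    rlang::abort("`components` must select at least one RC (empty group).")
  }
  components <- as.integer(components)
  if (anyNA(components) || anyDuplicated(components) ||
      any(components < 1L | components > object$rank)) {
    rlang::abort(sprintf(
      "`components` must be unique integers in [1, %d].", object$rank
    ))
  }
  v <- rowSums(object$components[, components, drop = FALSE])
  eeg_signal(v, fs = object$fs)
}

#' SSA components in long (tidy) form
#'
#' @param object An `eeg_ssa` fit.
#' @param components Optional integer vector of RC indices (default: all).
#' @return Tibble with columns `rc_index`, `sample_index`, `time`, `value_uV`.
#' @export
ssa_components <- function(object, components = NULL) {
  stopifnot(inherits(object, "eeg_ssa"))
  if (is.null(components)) components <- seq_len(object$rank)
  components <- as.integer(components)
  purrr::map_dfr(components, function(i) {
    tibble::tibble(
      rc_index = i,
      sample_index = seq_len(object$n),
      time = (seq_len(object$n) - 1) / object$fs,
      value_uV = object$components[, i]
    )
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an SSA decomposition
#'
#' One row per reconstructed component, in eigenvalue order.
#'
#' @param x An `eeg_ssa` fit.
#' @param ... Unused.
#' @return Tibble with `rc_index`, `eigenvalue`, `singular_value`,
#'   `energy_share`.
#' @method tidy eeg_ssa
#' @export
tidy.eeg_ssa <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  tibble::tibble(
    rc_index = seq_len(x$rank),
    eigenvalue = x$eigenvalues,
    singular_value = x$singular_values,
    energy_share = if (tot > 0) x$eigenvalues / tot else rep(0, x$rank)
  )
}

#' One-line summary of an SSA decomposition
#'
#' @inheritParams tidy.eeg_ssa
#' @return One-row tibble with `n`, `fs`, `L`, `K`, `rank`, `total_energy`.
#' @method glance eeg_ssa
#' @export
glance.eeg_ssa <- function(x, ...) {
  tibble::tibble(
    n = x$n, fs = x$fs, L = x$L, K = x$K, rank = x$rank,
    total_energy = sum(x$eigenvalues)
  )
}

#' Scree plot of an SSA decomposition
#'
#' @param object An `eeg_ssa` fit.
#' @param n_max Number of leading eigenvalues to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eeg_ssa
#' @export
autoplot.eeg_ssa <- function(object, n_max = 30, ...) {
  d <- tidy(object)
  d <- d[seq_len(min(nrow(d), n_max)), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rc_index, y = .data$eigenvalue)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "component index", y = expression(lambda[i]),
      title = sprintf("SSA eigenvalue spectrum (L = %d)", object$L)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
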