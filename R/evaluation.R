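#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is split into segments of
#' `segment_length` samples with 50% overlap, each segment is Hann-windowed,
#' and the one-sided periodograms are averaged with density scaling, giving
#' power in uV^2/Hz on a grid from 0 to fs/2. With the default segment length
#' `min(N, 2 * fs)` the frequency resolution is at least 0.5 Hz, fine enough
#' to localise rhythm peaks while still averaging several segments on typical
#' 8 s records. The integral of the PSD over frequency recovers the signal's
#' mean square power (Parseval).
#'
#' @inheritParams signal_fs
#' @param segment_length Samples per segment; default `min(N, 2 * fs)`.
#' @param overlap Fractional segment overlap in \[0, 1). Default 0.5.
#' @return A tibble of class `psd_estimate` with columns `frequency_hz` and
#'   `power` (uV^2/Hz); attributes `fs`, `segment_length`, `n_segments`,
#'   `window`.
#' @examples
#' x <- eeg_signal(sin(2 * pi * 10.5 * (0:1599) / 200), fs = 200)
#' psd <- estimate_psd(x)
#' psd$frequency_hz[which.max(psd$power)]
#' @export
estimate_psd <- function(x, fs = NULL, segment_length = NULL, overlap = 0.5) {
  fs <- signal_fs(x, fs)
  s <- signal_values(x)
  n <- length(s)
  if (n < 64) {
    rlang::abort("Series too short for PSD estimation (need N >= 64).")
  }
  if (is.null(segment_length)) {
    segment_length <- min(n, max(64L, round(2 * fs)))
  }
  m <- as.integer(segment_length)
  if (m < 8 || m > n) rlang::abort("`segment_length` must be in [8, N].")
  if (overlap < 0 || overlap >= 1) rlang::abort("`overlap` must be in [0, 1).")
  step <- max(1L, as.integer(round(m * (1 - overlap))))
  starts <- seq(1L, n - m + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / m)) # periodic Hann
  scale <- 1 / (fs * sum(w^2))
  n_half <- m %/% 2 + 1L
  acc <- numeric(n_half)
  for (st in starts) {
    seg <- s[st:(st + m - 1L)] * w
    p <- Mod(stats::fft(seg))^2 * scale
    acc <- acc + p[seq_len(n_half)]
  }
  pw <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when m is even)
  dbl <- rep(2, n_half)
  dbl[1] <- 1
  if (m %% 2 == 0) dbl[n_half] <- 1
  pw <- pw * dbl
  out <- tibble::tibble(
    frequency_hz = (seq_len(n_half) - 1) * fs / m,
    power = pw
  )
  attr(out, "fs") <- fs
  attr(out, "segment_length") <- m
  attr(out, "n_segments") <- length(starts)
  attr(out, "window") <- "hann"
  class(out) <- c("psd_estimate", class(out))
  out
}

#' Plot a PSD estimate
#'
#' @param object A `psd_estimate` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psd_estimate
#' @export
autoplot.psd_estimate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frequency_hz, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "frequency (Hz)", y = expression("PSD (" * mu * V^2 / Hz * ")")
    ) +
    ggplot2::theme_minimal()
}

#' Mean absolute PSD error between two spectra
#'
#' The reconstruction-error score for rhythm extraction: the mean over all
#' PSD bins of the absolute difference between the ground-truth rhythm's PSD
#' and the extracted rhythm's PSD, in uV^2/Hz. Both spectra must share the
#' same frequency grid (use identical estimator settings). Non-negative,
#' symmetric, and zero exactly when the spectra coincide.
#'
#' @param p_truth,p_extracted `psd_estimate` tibbles (or data frames with
#'   `frequency_hz` and `power` columns) on identical grids.
#' @return Scalar error in uV^2/Hz.
#' @export
eps_ave <- function(p_truth, p_extracted) {
  for (p in list(p_truth, p_extracted)) {
    if (!all(c("frequency_hz", "power") %in% names(p))) {
      rlang::abort("PSDs must have `frequency_hz` and `power` columns.")
    }
  }
  if (nrow(p_truth) != nrow(p_extracted) ||
      !isTRUE(all.equal(p_truth$frequency_hz, p_extracted$frequency_hz))) {
    rlang::abort("PSD frequency grids differ; use identical estimator settings.")
  }
  mean(abs(p_truth$power - p_extracted$power))
}

#' Mean square power of a signal
#'
#' P = sum(V^2) / N in uV^2, the characteristic feature used to separate
#' eyes-open from eyes-closed epochs by their alpha-rhythm strength.
#'
#' @inheritParams signal_fs
#' @return Scalar power (uV^2).
#' @export
rhythm_power <- function(x) {
  v <- signal_values(x)
  mean(v^2)
}

#' Band power from a PSD estimate
#'
#' Integrates the PSD over `[f_low, f_high]` by the trapezoidal rule.
#'
#' @param psd A `psd_estimate` tibble.
#' @param band A [rhythm_band()].
#' @return Band power in uV^2.
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(band, "rhythm_band"))
  keep <- psd$frequency_hz >= band$f_low & psd$frequency_hz <= band$f_high
  f <- psd$frequency_hz[keep]
  p <- psd$power[keep]
  if (length(f) < 2) return(0)
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Zero-phase IIR bandpass baseline
#'
#' The conventional comparator for SSA rhythm extraction: a 4th-order
#' Butterworth bandpass applied forward and backward (zero phase, 8th-order
#' magnitude response). A bandpass keeps everything inside the band —
#' including artifact and noise energy that overlaps the rhythm — which is
#' precisely the limitation subspace decomposition addresses.
#'
#' @inheritParams signal_fs
#' @param band A [rhythm_band()]; both edges must be below fs/2.
#' @param order Butterworth order (default 4).
#' @return An [eeg_signal()] tibble.
#' @export
iir_bandpass <- function(x, band, fs = NULL, order = 4) {
  stopifnot(inherits(band, "rhythm_band"))
  fs <- signal_fs(x, fs)
  s <- signal_values(x)
  if (band$f_high >= fs / 2) {
    rlang::abort(sprintf(
      "Band edge %g Hz is at or above Nyquist (%g Hz).", band$f_high, fs / 2
    ))
  }
  if (band$f_low <= 0) {
    rlang::abort("`f_low` must be positive for a bandpass design.")
  }
  bf <- signal::butter(order, c(band$f_low, band$f_high) / (fs / 2), type = "pass")
  eeg_signal(as.numeric(signal::filtfilt(bf, s)), fs = fs)
}

#' Threshold classification of epochs by rhythm power
#'
#' Epochs whose power exceeds the threshold are labelled `"eyes-closed"`
#' (strong alpha), the rest `"eyes-open"`.
#'
#' @param features A data frame with a `power_uV2` column (one row per
#'   epoch), e.g. from [run_state_classification()].
#' @param threshold Decision threshold in uV^2 (>= 0).
#' @return `features` with a `predicted_state` column added.
#' @examples
#' classify_by_threshold(data.frame(power_uV2 = c(5, 20)), threshold = 12)
#' @export
classify_by_threshold <- function(features, threshold) {
  if (!is.data.frame(features) || !"power_uV2" %in% names(features)) {
    rlang::abort("`features` must be a data frame with a `power_uV2` column.")
  }
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    rlang::abort("`threshold` must be a single non-negative number (uV^2).")
  }
  dplyr::mutate(
    tibble::as_tibble(features),
    predicted_state = ifelse(.data$power_uV2 > threshold, "eyes-closed", "eyes-open")
  )
}

#' Classification accuracy
#'
#' @param predicted,truth Equal-length vectors of state labels.
#' @return Fraction of matching labels in \[0, 1\].
#' @export
classification_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    rlang::abort("`predicted` and `truth` must have equal length.")
  }
  if (length(predicted) == 0) rlang::abort("Empty input.")
  mean(predicted == truth)
}

#' Exhaustive threshold sweep
#'
#' Evaluates every decision threshold that can change the labelling
#' (midpoints between consecutive sorted powers, plus one below the minimum
#' and one above the maximum) and reports the accuracy curve and the best
#' threshold. Ties in accuracy are broken toward the smallest threshold.
#'
#' @param features Data frame with `power_uV2` and `true_state` columns.
#' @return A list with `sweep` (tibble of `threshold`, `accuracy`),
#'   `best_threshold`, `best_accuracy`.
#' @export
sweep_threshold <- function(features) {
  if (!all(c("power_uV2", "true_state") %in% names(features))) {
    rlang::abort("`features` needs `power_uV2` and `true_state` columns.")
  }
  p <- sort(unique(features$power_uV2))
  cand <- c(max(p[1] / 2, p[1] - 1), (utils::head(p, -1) + utils::tail(p, -1)) / 2, p[length(p)] + 1)
  cand <- unique(pmax(cand, 0))
  acc <- vapply(cand, function(th) {
    lab <- ifelse(features$power_uV2 > th, "eyes-closed", "eyes-open")
    classification_accuracy(lab, features$true_state)
  }, numeric(1))
  best <- which.max(acc)
  list(
    sweep = tibble::tibble(threshold = cand, accuracy = acc),
    best_threshold = cand[best],
    best_accuracy = acc[best]
  )
}
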