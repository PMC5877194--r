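#' Extract a brain rhythm by adaptive SSA
#'
#' The full pipeline: time-delay embedding at L = ceiling(fs/fb) (unless `L`
#' is given), SVD, per-component PSD, adaptive grouping of the components
#' whose spectral peak falls in the band and clears the power thresholds, and
#' diagonal-averaged reconstruction of the grouped components.
#'
#' When no component qualifies the result is an all-zero series flagged with
#' the `empty_rhythm` attribute (query with [is_empty_rhythm()]) — a
#' legitimate "no in-band activity" outcome, distinct from an error.
#'
#' @inheritParams signal_fs
#' @param band A [rhythm_band()].
#' @param L Embedding dimension override; default `select_embedding(fs, fb)`.
#' @param min_peak_power,min_relative_power Grouping thresholds, see
#'   [grouping_params()].
#' @param segment_length Welch segment length for the per-component PSDs.
#' @return An [eeg_signal()] tibble with attributes `L`, `rc_selected`
#'   (integer vector of grouped component indices), `empty_rhythm` (logical)
#'   and `band`.
#' @examples
#' x <- eeg_signal(sin(2 * pi * 10.5 * (0:1599) / 200), fs = 200)
#' alpha <- extract_rhythm(x, rhythm_band("alpha"))
#' selected_components(alpha)
#' @export
extract_rhythm <- function(x, band, L = NULL, fs = NULL,
                           min_peak_power = 0.5, min_relative_power = 0.02,
                           segment_length = NULL) {
  stopifnot(inherits(band, "rhythm_band"))
  fs <- signal_fs(x, fs)
  s <- signal_values(x)
  if (is.null(L)) L <- select_embedding(fs, band$fb)
  fit <- ssa(s, L = L, fs = fs)
  params <- grouping_params(band, min_peak_power, min_relative_power)
  if (fit$rank == 0) {
    sel <- integer(0)
  } else {
    spectra <- component_spectra(fit, segment_length = segment_length)
    sel <- select_rhythm_components(spectra, params)
  }
  out <- if (length(sel) == 0) {
    eeg_signal(rep(0, length(s)), fs = fs)
  } else {
    ssa_reconstruct(fit, sel)
  }
  attr(out, "L") <- as.integer(L)
  attr(out, "rc_selected") <- sel
  attr(out, "empty_rhythm") <- length(sel) == 0
  attr(out, "band") <- band
  out
}

#' @rdname extract_rhythm
#' @export
is_empty_rhythm <- function(x) {
  isTRUE(attr(x, "empty_rhythm"))
}

#' @rdname extract_rhythm
#' @export
selected_components <- function(x) {
  attr(x, "rc_selected")
}
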