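#' Define a frequency band of interest
#'
#' Named EEG bands follow the conventional ranges: delta 1-4 Hz, theta
#' 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz. The bandwidth `fb = f_high - f_low`
#' drives the embedding-dimension rule L = ceiling(fs/fb).
#'
#' @param name One of `"delta"`, `"theta"`, `"alpha"`, `"beta"`, or any label
#'   when `f_low`/`f_high` are given explicitly.
#' @param f_low,f_high Band edges in Hz (required for custom bands).
#' @return An object of class `rhythm_band` with fields `name`, `f_low`,
#'   `f_high`, `fb`.
#' @examples
#' rhythm_band("alpha")
#' rhythm_band("mu", 8, 12)
#' @export
rhythm_band <- function(name, f_low = NULL, f_high = NULL) {
  named <- list(
    delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30)
  )
  if (is.null(f_low) || is.null(f_high)) {
    if (!name %in% names(named)) {
      rlang::abort(
        "Unknown band name; supply `f_low` and `f_high` for custom bands."
      )
    }
    f_low <- named[[name]][1]
    f_high <- named[[name]][2]
  }
  if (!is.numeric(f_low) || !is.numeric(f_high) || f_low < 0 || f_high <= f_low) {
    rlang::abort("Band edges must satisfy 0 <= f_low < f_high.")
  }
  structure(
    list(name = name, f_low = f_low, f_high = f_high, fb = f_high - f_low),
    class = "rhythm_band"
  )
}

#' @export
print.rhythm_band <- function(x, ...) {
  cat(sprintf(
    "<rhythm_band> %s: [%g, %g] Hz (fb = %g Hz)\n",
    x$name, x$f_low, x$f_high, x$fb
  ))
  invisible(x)
}

#' Grouping thresholds for adaptive component selection
#'
#' A reconstructed component joins the rhythm group when its PSD peak lies in
#' the band AND its peak power clears both an absolute floor and a fraction of
#' the strongest component's peak. The defaults separate genuine rhythm
#' components (peaks of a few uV^2/Hz and up) from residual noise components
#' (peaks well below 1 uV^2/Hz).
#'
#' @param band A [rhythm_band()].
#' @param min_peak_power Absolute floor on the RC's PSD peak (uV^2/Hz).
#' @param min_relative_power Required fraction (in \[0, 1\]) of the largest
#'   RC peak power across all components.
#' @return An object of class `grouping_params`.
#' @export
grouping_params <- function(band, min_peak_power = 0.5, min_relative_power = 0.02) {
  stopifnot(inherits(band, "rhythm_band"))
  if (min_peak_power < 0 || min_relative_power < 0 || min_relative_power > 1) {
    rlang::abort(
      "`min_peak_power` must be >= 0 and `min_relative_power` in [0, 1]."
    )
  }
  structure(
    list(
      band = band,
      min_peak_power = min_peak_power,
      min_relative_power = min_relative_power
    ),
    class = "grouping_params"
  )
}

#' Per-component spectra of an SSA decomposition
#'
#' Estimates the Welch PSD of every reconstructed component and summarises
#' each by its spectral peak; this is the evidence the adaptive grouping rule
#' acts on.
#'
#' @param object An `eeg_ssa` fit.
#' @param ... Passed to [estimate_psd()] (e.g. `segment_length`).
#' @return A tibble with one row per RC: `rc_index`, `eigenvalue`,
#'   `peak_frequency` (Hz), `peak_power` (uV^2/Hz), and a `psd` list-column
#'   of per-component PSD tibbles.
#' @export
component_spectra <- function(object, ...) {
  stopifnot(inherits(object, "eeg_ssa"))
  if (object$rank == 0) {
    rlang::abort("Decomposition has no components (zero input).")
  }
  purrr::map_dfr(seq_len(object$rank), function(i) {
    psd <- estimate_psd(object$components[, i], fs = object$fs, ...)
    peak <- which.max(psd$power)
    tibble::tibble(
      rc_index = i,
      eigenvalue = object$eigenvalues[i],
      peak_frequency = psd$frequency_hz[peak],
      peak_power = psd$power[peak],
      psd = list(psd)
    )
  })
}

#' Select the components that form a rhythm
#'
#' Applies the adaptive grouping rule to a component-spectra table: keep every
#' RC whose PSD peak frequency falls inside the band and whose peak power
#' passes `max(min_peak_power, min_relative_power * max peak power)`. The
#' selection is deterministic and preserves component order. An empty
#' selection is a legal result (the signal has no energy in the band), not an
#' error.
#'
#' Eigenvalue pairing (an oscillatory source shows up as two nearly equal
#' eigenvalues) is visible in the spectra table but does not override the
#' frequency criterion.
#'
#' @param spectra Output of [component_spectra()].
#' @param params A [grouping_params()].
#' @return Integer vector of selected 1-based RC indices (possibly empty).
#' @export
select_rhythm_components <- function(spectra, params) {
  stopifnot(inherits(params, "grouping_params"))
  if (!all(c("rc_index", "peak_frequency", "peak_power") %in% names(spectra))) {
    rlang::abort(
      "`spectra` must have columns rc_index, peak_frequency, peak_power."
    )
  }
  if (nrow(spectra) == 0) return(integer(0))
  floor_power <- max(
    params$min_peak_power,
    params$min_relative_power * max(spectra$peak_power)
  )
  keep <- spectra$peak_frequency >= params$band$f_low &
    spectra$peak_frequency <= params$band$f_high &
    spectra$peak_power >= floor_power
  as.integer(spectra$rc_index[keep])
}
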