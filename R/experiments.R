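#' Reconstruction error across embedding dimensions
#'
#' For each seed, simulates an EEG record, extracts the alpha (or other)
#' rhythm at every requested embedding dimension, and scores the extraction
#' by the mean absolute PSD error against the simulation's clean rhythm
#' channel. This reproduces, at configurable replication, the error-vs-L
#' curves that motivate the L = fs/fb rule: the error is minimised near
#' L = fs/fb and degrades for much larger L once artifacts and noise are
#' present (component mixing).
#'
#' @param L_values Integer vector of embedding dimensions to sweep.
#' @param seeds Integer vector of simulation seeds (one record per seed).
#' @param preset Simulator preset, see [mpa_config()].
#' @param band Rhythm to extract; default alpha. The ground-truth channel is
#'   the simulation column with the band's name.
#' @param fs,duration Passed to [mpa_config()].
#' @param ... Further arguments to [extract_rhythm()] (thresholds, etc.).
#' @return Tibble with columns `preset`, `seed`, `L`, `eps_ave`,
#'   `n_components`.
#' @export
run_embedding_sweep <- function(L_values, seeds, preset = "spontaneous",
                                band = rhythm_band("alpha"),
                                fs = 200, duration = 8, ...) {
  stopifnot(inherits(band, "rhythm_band"))
  purrr::map_dfr(seeds, function(sd) {
    sim <- simulate_eeg(mpa_config(preset, seed = sd, fs = fs, duration = duration))
    truth <- sim_channel(sim, band$name)
    p_truth <- estimate_psd(truth)
    eeg <- sim_channel(sim, "eeg")
    purrr::map_dfr(L_values, function(L) {
      rec <- extract_rhythm(eeg, band, L = L, ...)
      tibble::tibble(
        preset = preset, seed = sd, L = as.integer(L),
        eps_ave = eps_ave(p_truth, estimate_psd(rec)),
        n_components = length(selected_components(rec))
      )
    })
  })
}

#' Plot an embedding-dimension sweep
#'
#' @param sweep Output of [run_embedding_sweep()].
#' @return A ggplot object: per-seed error curves plus the median.
#' @export
plot_embedding_sweep <- function(sweep) {
  med <- dplyr::summarise(
    dplyr::group_by(sweep, .data$L),
    eps_ave = stats::median(.data$eps_ave), .groups = "drop"
  )
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$L, y = .data$eps_ave)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$seed), alpha = 0.3) +
    ggplot2::geom_line(data = med, colour = "red", linewidth = 1) +
    ggplot2::labs(
      x = "embedding dimension L",
      y = expression(epsilon[ave] ~ "(" * mu * V^2 / Hz * ")")
    ) +
    ggplot2::theme_minimal()
}

#' Eyes-open vs eyes-closed classification experiment
#'
#' Simulates `n_per_class` eyes-open and `n_per_class` eyes-closed epochs
#' (the eyes-open preset attenuates the alpha innovation s.d. by
#' `open_alpha_scale`), extracts the alpha rhythm from each epoch by adaptive
#' SSA and by the zero-phase IIR bandpass baseline, computes the mean square
#' power P = sum(V^2)/N of each extraction, and finds each method's best
#' decision threshold by exhaustive sweep.
#'
#' @param n_per_class Epochs per state. Default 30.
#' @param seeds Integer seeds, length `2 * n_per_class`; the first half are
#'   eyes-open epochs, the second half eyes-closed. Default `1:(2*n)`.
#' @param band Rhythm band; default alpha.
#' @param L Embedding override for the SSA extraction (default fs/fb rule).
#' @param fs,duration,open_alpha_scale Passed to [mpa_config()].
#' @param methods Subset of `c("ssa", "iir")`.
#' @return An object of class `state_classification`: list with `features`
#'   (tibble: `epoch_id`, `seed`, `method`, `true_state`, `power_uV2`,
#'   `predicted_state`) and `results` (tibble: `method`, `best_threshold`,
#'   `accuracy`). `tidy()` returns the features, `glance()` the results.
#' @export
run_state_classification <- function(n_per_class = 30, seeds = NULL,
                                     band = rhythm_band("alpha"), L = NULL,
                                     fs = 200, duration = 8,
                                     open_alpha_scale = 0.3,
                                     methods = c("ssa", "iir")) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(seeds)) seeds <- seq_len(2 * n_per_class)
  if (length(seeds) != 2 * n_per_class) {
    rlang::abort("`seeds` must have length 2 * n_per_class.")
  }
  states <- rep(c("eyes-open", "eyes-closed"), each = n_per_class)
  features <- purrr::map_dfr(seq_along(seeds), function(i) {
    preset <- if (states[i] == "eyes-open") "eyes-open" else "eyes-closed"
    cfg <- mpa_config(
      preset, seed = seeds[i], fs = fs, duration = duration,
      open_alpha_scale = open_alpha_scale
    )
    eeg <- sim_channel(simulate_eeg(cfg), "eeg")
    purrr::map_dfr(methods, function(m) {
      rec <- switch(m,
        ssa = extract_rhythm(eeg, band, L = L),
        iir = iir_bandpass(eeg, band)
      )
      tibble::tibble(
        epoch_id = i, seed = seeds[i], method = m,
        true_state = states[i], power_uV2 = rhythm_power(rec)
      )
    })
  })
  results <- purrr::map_dfr(methods, function(m) {
    f <- dplyr::filter(features, .data$method == m)
    sw <- sweep_threshold(f)
    tibble::tibble(
      method = m,
      best_threshold = sw$best_threshold,
      accuracy = sw$best_accuracy
    )
  })
  features <- dplyr::left_join(features, results, by = "method")
  features$predicted_state <- ifelse(
    features$power_uV2 > features$best_threshold, "eyes-closed", "eyes-open"
  )
  features$best_threshold <- NULL
  features$accuracy <- NULL
  structure(
    list(features = features, results = results),
    class = "state_classification"
  )
}

#' @export
print.state_classification <- function(x, ...) {
  cat("<state_classification>", nrow(x$features), "epoch-method features\n")
  print(x$results)
  invisible(x)
}

#' @rdname run_state_classification
#' @param x A `state_classification` object.
#' @param ... Unused.
#' @method tidy state_classification
#' @export
tidy.state_classification <- function(x, ...) x$features

#' @rdname run_state_classification
#' @method glance state_classification
#' @export
glance.state_classification <- function(x, ...) x$results

#' @rdname run_state_classification
#' @param object A `state_classification` object.
#' @method autoplot state_classification
#' @export
autoplot.state_classification <- function(object, ...) {
  ggplot2::ggplot(
    object$features,
    ggplot2::aes(x = .data$epoch_id, y = .data$power_uV2, colour = .data$true_state)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      data = object$results,
      ggplot2::aes(yintercept = .data$best_threshold),
      linetype = 2
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$method), scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "epoch", y = expression("alpha power (" * mu * V^2 * ")"),
      colour = "state"
    ) +
    ggplot2::theme_minimal()
}
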