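#' Parameters of one Markov-amplitude rhythm
#'
#' Each simulated brain rhythm is a sinusoid at frequency `f` whose amplitude
#' follows a first-order autoregressive (Markov) process
#' a(n+1) = gamma * a(n) + xi(n), with xi zero-mean Gaussian of s.d.
#' `sigma_xi`. `gamma` in (0, 1) sets the amplitude correlation between
#' steps; `sigma_xi` the strength of the stochastic modulation.
#'
#' @param name Rhythm label (used to key the rhythm's random sub-stream).
#' @param f Oscillation frequency (Hz, > 0).
#' @param gamma Amplitude correlation, strictly inside (0, 1).
#' @param sigma_xi Innovation standard deviation (uV, >= 0).
#' @param theta Initial phase (rad); default 0.
#' @return An object of class `rhythm_params`.
#' @export
rhythm_params <- function(name, f, gamma, sigma_xi, theta = 0) {
  if (!is.numeric(f) || f <= 0) rlang::abort("`f` must be positive (Hz).")
  if (!is.numeric(gamma) || gamma <= 0 || gamma >= 1) {
    rlang::abort(
      "`gamma` must lie strictly in (0, 1): the Markov amplitude recursion a(n+1) = gamma a(n) + xi(n) is only stationary for 0 < gamma < 1."
    )
  }
  if (!is.numeric(sigma_xi) || sigma_xi < 0) {
    rlang::abort("`sigma_xi` must be >= 0 (uV).")
  }
  structure(
    list(name = name, f = f, gamma = gamma, sigma_xi = sigma_xi, theta = theta),
    class = "rhythm_params"
  )
}

#' The four standard simulated rhythms
#'
#' Delta (2.5 Hz), theta (6 Hz), alpha (10.5 Hz) and beta (21.5 Hz) rhythms
#' with their oscillation frequencies at the midpoints of the conventional
#' EEG bands and Markov-amplitude parameters calibrated so the simulated
#' spontaneous EEG has a realistic resting-state spectrum (alpha dominant,
#' weak beta).
#'
#' @return Named list of [rhythm_params()].
#' @export
mpa_rhythms <- function() {
  list(
    delta = rhythm_params("delta", f = 2.50, gamma = 0.99, sigma_xi = 2.26),
    theta = rhythm_params("theta", f = 6.00, gamma = 0.97, sigma_xi = 2.78),
    alpha = rhythm_params("alpha", f = 10.50, gamma = 0.99, sigma_xi = 2.35),
    beta  = rhythm_params("beta",  f = 21.50, gamma = 0.99, sigma_xi = 0.36)
  )
}

#' Artifact parameters: ocular pulses and baseline drift
#'
#' The electrooculogram (EOG, eye blinks) is modelled as periodic symmetric
#' triangular pulses of amplitude `v_eog`, period `t_eog` and base width
#' `w_eog`, zero between pulses. Baseline drift (head/body movement) is a
#' low-frequency sinusoid of amplitude `v_bd` and frequency `f_bd`.
#'
#' @param v_eog EOG peak amplitude (uV). Default 50.
#' @param t_eog EOG pulse period (s). Default 3.
#' @param w_eog EOG pulse base width (s), < `t_eog`. Default 0.3.
#' @param v_bd Drift amplitude (uV). Default 10.
#' @param f_bd Drift frequency (Hz). Default 0.5.
#' @return An object of class `artifact_params`.
#' @export
artifact_params <- function(v_eog = 50, t_eog = 3, w_eog = 0.3,
                            v_bd = 10, f_bd = 0.5) {
  vals <- c(v_eog, t_eog, w_eog, v_bd, f_bd)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    rlang::abort("All artifact parameters must be finite and non-negative.")
  }
  if (w_eog >= t_eog) rlang::abort("`w_eog` must be smaller than `t_eog`.")
  structure(
    list(v_eog = v_eog, t_eog = t_eog, w_eog = w_eog, v_bd = v_bd, f_bd = f_bd),
    class = "artifact_params"
  )
}

#' Full simulator configuration
#'
#' Assembles the rhythm set, artifact parameters, white-noise power, sampling
#' rate, duration and master seed into one configuration. Presets:
#'
#' * `"spontaneous"`: the four rhythms only (no artifacts, no noise).
#' * `"full"` / `"eyes-closed"`: rhythms + EOG + drift + Gaussian noise.
#' * `"eyes-open"`: as `"full"` but with the alpha innovation s.d. scaled by
#'   `open_alpha_scale` (default 0.3), emulating the attenuation of the alpha
#'   rhythm under visual attention.
#'
#' White-noise power is given on a decibel scale relative to 1 uV^2:
#' variance = 10^(noise_power_db / 10) uV^2.
#'
#' @param preset One of `"full"`, `"spontaneous"`, `"eyes-closed"`,
#'   `"eyes-open"`.
#' @param seed Master integer seed; every stochastic channel derives its own
#'   sub-stream from it, keyed by channel name.
#' @param fs Sampling rate (Hz). Default 200.
#' @param duration Record length (s). Default 8.
#' @param rhythms Named list of [rhythm_params()]; default [mpa_rhythms()].
#' @param artifacts An [artifact_params()].
#' @param noise_power_db White-noise power in dB re 1 uV^2. Default 1.
#' @param open_alpha_scale Alpha `sigma_xi` multiplier for the eyes-open
#'   preset.
#' @return An object of class `mpa_config`.
#' @examples
#' cfg <- mpa_config("spontaneous", seed = 7)
#' sim <- simulate_eeg(cfg)
#' @export
mpa_config <- function(preset = c("full", "spontaneous", "eyes-closed", "eyes-open"),
                       seed = 1, fs = 200, duration = 8,
                       rhythms = mpa_rhythms(), artifacts = artifact_params(),
                       noise_power_db = 1, open_alpha_scale = 0.3) {
  preset <- match.arg(preset)
  stopifnot(inherits(artifacts, "artifact_params"))
  if (!is.numeric(fs) || fs <= 0 || !is.numeric(duration) || duration <= 0) {
    rlang::abort("`fs` and `duration` must be positive.")
  }
  fmax <- max(vapply(rhythms, function(r) r$f, numeric(1)))
  if (fs <= 2 * fmax) {
    rlang::abort(sprintf(
      "fs = %g Hz must exceed twice the fastest rhythm frequency (%g Hz).",
      fs, fmax
    ))
  }
  if (preset == "eyes-open") {
    a <- rhythms$alpha
    rhythms$alpha <- rhythm_params(
      a$name, a$f, a$gamma, a$sigma_xi * open_alpha_scale, a$theta
    )
  }
  include <- preset != "spontaneous"
  structure(
    list(
      preset = preset, seed = as.integer(seed), fs = fs, duration = duration,
      rhythms = rhythms, artifacts = artifacts,
      noise_power_db = noise_power_db,
      include_artifacts = include, include_noise = include
    ),
    class = "mpa_config"
  )
}

# Deterministic sub-seed in [0, 2^31 - 2], keyed by channel name so that the
# stream a rhythm receives does not depend on its position in the list.
derive_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  # doubles are exact far beyond (2^31) * 48271, so this stays integer-exact
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + h) %% 2147483647)
}

#' First-order Markov (AR(1)) amplitude process
#'
#' Generates a(1) = a0, a(n+1) = gamma * a(n) + xi(n) with xi ~ N(0,
#' sigma_xi^2). When `a0` is omitted it is drawn from the stationary
#' distribution N(0, sigma_xi^2 / (1 - gamma^2)), which avoids any burn-in
#' transient in short records.
#'
#' @inheritParams rhythm_params
#' @param n_samples Length of the amplitude series.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param a0 Optional initial amplitude; default stationary draw (0 when
#'   `sigma_xi` is 0).
#' @return Numeric vector of length `n_samples`.
#' @examples
#' markov_amplitude(0.5, 0, 4, a0 = 5) # 5, 2.5, 1.25, 0.625
#' @export
markov_amplitude <- function(gamma, sigma_xi, n_samples, seed = NULL, a0 = NULL) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0 || gamma >= 1) {
    rlang::abort(
      "`gamma` must lie strictly in (0, 1) for a stationary Markov amplitude."
    )
  }
  if (sigma_xi < 0) rlang::abort("`sigma_xi` must be >= 0.")
  n_samples <- as.integer(n_samples)
  gen <- function() {
    start <- if (!is.null(a0)) {
      a0
    } else if (sigma_xi == 0) {
      0
    } else {
      stats::rnorm(1, 0, sigma_xi / sqrt(1 - gamma^2))
    }
    innov <- if (n_samples > 1) stats::rnorm(n_samples - 1, 0, sigma_xi) else numeric(0)
    as.numeric(stats::filter(c(start, innov), gamma, method = "recursive"))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Simulate a single Markov-amplitude rhythm
#'
#' The elementwise product of a [markov_amplitude()] series and the sinusoid
#' sin(2 pi f t + theta).
#'
#' @param p A [rhythm_params()].
#' @param fs Sampling rate (Hz).
#' @param duration Length in seconds.
#' @param seed Optional integer seed.
#' @param a0 Optional initial amplitude (see [markov_amplitude()]).
#' @return An [eeg_signal()] tibble.
#' @export
simulate_rhythm <- function(p, fs, duration, seed = NULL, a0 = NULL) {
  stopifnot(inherits(p, "rhythm_params"))
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  amp <- markov_amplitude(p$gamma, p$sigma_xi, n, seed = seed, a0 = a0)
  eeg_signal(amp * sin(2 * pi * p$f * t + p$theta), fs = fs)
}

#' Periodic triangular EOG pulse train
#'
#' Symmetric triangular pulses of peak `v_eog` and base width `w_eog`, zero
#' between pulses, with the first apex at `t_eog / 2` and one apex every
#' `t_eog` seconds thereafter.
#'
#' @param a An [artifact_params()].
#' @inheritParams simulate_rhythm
#' @return An [eeg_signal()] tibble.
#' @export
eog_waveform <- function(a, fs, duration) {
  stopifnot(inherits(a, "artifact_params"))
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  u <- (t - a$t_eog / 2) %% a$t_eog
  dist_to_apex <- pmin(u, a$t_eog - u)
  v <- if (a$w_eog > 0) {
    a$v_eog * pmax(0, 1 - dist_to_apex / (a$w_eog / 2))
  } else {
    rep(0, n)
  }
  eeg_signal(v, fs = fs)
}

#' Sinusoidal baseline drift
#'
#' v_bd * sin(2 pi f_bd t): a slow wander emulating head or body movement.
#'
#' @inheritParams eog_waveform
#' @return An [eeg_signal()] tibble.
#' @export
baseline_drift <- function(a, fs, duration) {
  stopifnot(inherits(a, "artifact_params"))
  n <- round(fs * duration)
  t <- (seq_len(n) - 1) / fs
  eeg_signal(a$v_bd * sin(2 * pi * a$f_bd * t), fs = fs)
}

#' Gaussian measurement noise
#'
#' I.i.d. zero-mean Gaussian samples with variance 10^(power_db/10) uV^2
#' (decibels re 1 uV^2).
#'
#' @param power_db Noise power in dB re 1 uV^2.
#' @inheritParams simulate_rhythm
#' @return An [eeg_signal()] tibble.
#' @export
white_noise <- function(power_db, fs, duration, seed = NULL) {
  n <- round(fs * duration)
  sd <- sqrt(10^(power_db / 10))
  gen <- function() stats::rnorm(n, 0, sd)
  v <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  eeg_signal(v, fs = fs)
}

# All per-channel series for a configuration, as a named list of numeric
# vectors. Each stochastic channel gets its own sub-stream keyed by name.
mpa_channels <- function(cfg) {
  stopifnot(inherits(cfg, "mpa_config"))
  n <- round(cfg$fs * cfg$duration)
  rhythm_series <- lapply(cfg$rhythms, function(p) {
    signal_values(simulate_rhythm(
      p, cfg$fs, cfg$duration,
      seed = derive_seed(cfg$seed, paste0("rhythm_", p$name))
    ))
  })
  names(rhythm_series) <- vapply(cfg$rhythms, function(p) p$name, character(1))
  spont <- Reduce(`+`, rhythm_series, accumulate = FALSE)
  eog <- drift <- noise <- rep(0, n)
  if (cfg$include_artifacts) {
    eog <- signal_values(eog_waveform(cfg$artifacts, cfg$fs, cfg$duration))
    drift <- signal_values(baseline_drift(cfg$artifacts, cfg$fs, cfg$duration))
  }
  if (cfg$include_noise) {
    noise <- signal_values(white_noise(
      cfg$noise_power_db, cfg$fs, cfg$duration,
      seed = derive_seed(cfg$seed, "noise")
    ))
  }
  c(
    list(eeg = spont + eog + drift + noise, spontaneous = spont),
    rhythm_series,
    list(eog = eog, drift = drift, noise = noise)
  )
}

#' Simulate the spontaneous EEG (rhythm superposition only)
#'
#' @param cfg An [mpa_config()].
#' @return An [eeg_signal()] tibble: the sum of the configured rhythms, no
#'   artifacts or noise.
#' @export
simulate_spontaneous <- function(cfg) {
  ch <- mpa_channels(cfg)
  eeg_signal(ch$spontaneous, fs = cfg$fs)
}

#' Simulate a full EEG record with component breakdown
#'
#' The composite signal is the superposition of the Markov-amplitude rhythms
#' plus (per configuration) EOG pulses, baseline drift and Gaussian noise.
#' All channels are returned side by side so extraction error can be measured
#' against the clean ground-truth rhythm.
#'
#' @param cfg An [mpa_config()].
#' @return A tibble of class `mpa_simulation` with columns `time`, `eeg`,
#'   `spontaneous`, one column per rhythm, `eog`, `drift`, `noise`;
#'   attributes `fs` and `config`.
#' @examples
#' sim <- simulate_eeg(mpa_config("full", seed = 1))
#' sim_channel(sim, "alpha")
#' @export
simulate_eeg <- function(cfg) {
  ch <- mpa_channels(cfg)
  n <- length(ch$eeg)
  out <- tibble::tibble(time = (seq_len(n) - 1) / cfg$fs, !!!ch)
  attr(out, "fs") <- cfg$fs
  attr(out, "config") <- cfg
  class(out) <- c("mpa_simulation", class(out))
  out
}

#' Extract one channel of a simulation as a signal
#'
#' @param sim An `mpa_simulation` tibble from [simulate_eeg()].
#' @param channel Column name (`"eeg"`, `"alpha"`, `"spontaneous"`, ...).
#' @param fs Sampling rate; taken from `sim` when omitted.
#' @return An [eeg_signal()] tibble.
#' @export
sim_channel <- function(sim, channel, fs = NULL) {
  if (!channel %in% names(sim)) {
    rlang::abort(sprintf("No channel `%s` in simulation.", channel))
  }
  eeg_signal(sim[[channel]], fs = signal_fs(sim, fs))
}

#' Plot a simulated EEG record channel-by-channel
#'
#' @param object An `mpa_simulation` from [simulate_eeg()].
#' @param channels Character vector of channels to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpa_simulation
#' @export
autoplot.mpa_simulation <- function(object,
                                    channels = c("eeg", "spontaneous", "alpha", "eog", "drift"),
                                    ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), dplyr::all_of(c("time", channels))),
    -"time",
    names_to = "channel", values_to = "value_uV"
  )
  d$channel <- factor(d$channel, levels = channels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$value_uV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}
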