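#' Construct a single-channel EEG signal tibble
#'
#' The package's canonical time-series container is a plain tibble with a
#' `time` column (seconds) and a `value_uV` column (microvolts), so that all
#' dplyr/tidyr verbs apply directly. The sampling rate is carried both as the
#' `fs` attribute and implicitly in the `time` column spacing; downstream
#' functions recover it from either, so piping through verbs that drop
#' attributes is safe.
#'
#' @param values Numeric vector of samples in microvolts. Must be finite and
#'   of length at least 2.
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#'
#' @return A tibble with columns `time` and `value_uV` and attribute `fs`.
#' @examples
#' x <- eeg_signal(sin(2 * pi * 10 * (0:399) / 200), fs = 200)
#' signal_fs(x)
#' @export
eeg_signal <- function(values, fs, start_time = 0) {
  values <- as.numeric(values)
  if (length(values) < 2) {
    rlang::abort("`values` must contain at least 2 samples.")
  }
  if (!all(is.finite(values))) {
    rlang::abort("`values` must be finite (no NA/NaN/Inf).")
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    rlang::abort("`fs` must be a single positive number (Hz).")
  }
  out <- tibble::tibble(
    time = start_time + (seq_along(values) - 1) / fs,
    value_uV = values
  )
  attr(out, "fs") <- fs
  out
}

#' Recover the sampling rate of a signal
#'
#' Reads the `fs` attribute if present, otherwise infers it from the median
#' spacing of the `time` column. An explicit `fs` argument always wins.
#'
#' @param x A data frame with `time`/`value_uV` columns, or a numeric vector.
#' @param fs Optional explicit sampling rate (Hz); returned as-is when given.
#' @return Sampling rate in Hz.
#' @export
signal_fs <- function(x, fs = NULL) {
  if (!is.null(fs)) {
    if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
      rlang::abort("`fs` must be a single positive number (Hz).")
    }
    return(as.numeric(fs))
  }
  a <- attr(x, "fs")
  if (!is.null(a)) {
    return(as.numeric(a))
  }
  if (is.data.frame(x) && "time" %in% names(x) && nrow(x) >= 2) {
    dt <- stats::median(diff(x$time))
    if (is.finite(dt) && dt > 0) {
      return(1 / dt)
    }
  }
  rlang::abort(
    "Cannot determine the sampling rate: supply `fs` or a signal with a `time` column."
  )
}

#' Extract the sample vector from a signal
#'
#' Accepts either the tibble produced by [eeg_signal()] (column `value_uV`)
#' or a bare numeric vector, and validates finiteness.
#'
#' @inheritParams signal_fs
#' @return Numeric vector of samples (microvolts).
#' @export
signal_values <- function(x) {
  v <- if (is.data.frame(x)) {
    if (!"value_uV" %in% names(x)) {
      rlang::abort("Signal data frame must have a `value_uV` column.")
    }
    x$value_uV
  } else if (is.numeric(x)) {
    as.numeric(x)
  } else {
    rlang::abort("`x` must be a signal data frame or a numeric vector.")
  }
  if (!all(is.finite(v))) {
    rlang::abort("Signal values must be finite (no NA/NaN/Inf).")
  }
  v
}

#' Read / write single-channel EEG CSV
#'
#' The interchange format is a one-column CSV `value_uV` preceded by a comment
#' line `# fs_hz=<float>` carrying the sampling rate. Files without a parsable
#' `fs_hz` header are rejected: a sample vector without its sampling rate is
#' not a signal.
#'
#' @param path File path.
#' @return `read_eeg_csv()` returns an [eeg_signal()] tibble.
#' @export
read_eeg_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path))
  }
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("^#\\s*fs_hz\\s*=\\s*([0-9.eE+-]+)", header))[[1]]
  if (length(m) < 2) {
    rlang::abort(
      "Missing sampling rate: first line must be a `# fs_hz=<float>` comment."
    )
  }
  fs <- suppressWarnings(as.numeric(m[2]))
  if (!is.finite(fs) || fs <= 0) {
    rlang::abort("Invalid `fs_hz` value in header comment.")
  }
  dat <- utils::read.csv(path, comment.char = "#")
  if (!"value_uV" %in% names(dat)) {
    rlang::abort("EEG CSV must have a `value_uV` column.")
  }
  if (!is.numeric(dat$value_uV) || anyNA(dat$value_uV)) {
    rlang::abort("`value_uV` column must be numeric with no missing values.")
  }
  eeg_signal(dat$value_uV, fs = fs)
}

#' @rdname read_eeg_csv
#' @param x Signal to write (data frame with `value_uV`, or numeric vector).
#' @param fs Sampling rate in Hz; taken from `x` when omitted.
#' @return `write_eeg_csv()` returns `path` invisibly.
#' @export
write_eeg_csv <- function(x, path, fs = NULL) {
  fs <- signal_fs(x, fs)
  v <- signal_values(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs_hz=%.10g", fs), con)
  utils::write.csv(data.frame(value_uV = v), con, row.names = FALSE)
  invisible(path)
}
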