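#' Construct a single-lead ECG signal
#'
#' A lightweight container for a sampled amplitude series. Amplitudes are in
#' arbitrary units before preprocessing and dimensionless in \[-1, 1\] after
#' [normalize_amplitude()].
#'
#' @param samples Numeric vector of amplitudes, length >= 2.
#' @param fs Sampling frequency in Hz (MIT-BIH records use 360).
#' @param label Free-text record identifier.
#' @return An `ecg_signal` object: the numeric vector with `fs` and `label`
#'   attributes.
#' @examples
#' sig <- ecg_signal(sin(2 * pi * 10 * seq(0, 1, by = 1 / 360)), fs = 360)
#' sig
#' @export
ecg_signal <- function(samples, fs, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("an ECG signal needs at least 2 samples", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (anyNA(samples)) stop("signal contains missing values", call. = FALSE)
  structure(samples, fs = as.numeric(fs), label = as.character(label),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.2f s)%s\n",
              length(x), signal_fs(x), length(x) / signal_fs(x),
              if (nzchar(signal_label(x))) paste0(" [", signal_label(x), "]") else ""))
  utils::str(unclass(x)[seq_len(min(length(x), 10L))])
  invisible(x)
}

#' Sampling frequency of an ECG signal
#' @param signal An `ecg_signal`.
#' @return Sampling frequency in Hz.
#' @export
signal_fs <- function(signal) attr(signal, "fs")

#' Record label of an ECG signal
#' @param signal An `ecg_signal`.
#' @return Character label.
#' @export
signal_label <- function(signal) attr(signal, "label") %||% ""

#' @export
`[.ecg_signal` <- function(x, i, ...) {
  ecg_signal(unclass(x)[i], fs = signal_fs(x), label = signal_label(x))
}

#' Coerce an ECG signal to a tibble
#'
#' @param x An `ecg_signal`.
#' @param ... Unused.
#' @return A tibble with columns `sample` (0-based index), `time` (seconds)
#'   and `amplitude`.
#' @exportS3Method tibble::as_tibble
as_tibble.ecg_signal <- function(x, ...) {
  idx <- seq_along(x) - 1L
  tibble::tibble(sample = idx, time = idx / signal_fs(x),
                 amplitude = as.numeric(x))
}

# replace samples, keep metadata
set_samples <- function(signal, samples) {
  ecg_signal(samples, fs = signal_fs(signal), label = signal_label(signal))
}

as_ecg_signal <- function(x, fs, label = "") {
  if (inherits(x, "ecg_signal")) x else ecg_signal(x, fs = fs, label = label)
}
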