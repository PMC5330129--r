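#' Band-pass filter specification
#'
#' The QRS complex concentrates its energy in roughly the 5--15 Hz band;
#' band-pass filtering there suppresses baseline wander, powerline
#' interference, muscle noise and most of the T wave before lexical analysis.
#'
#' @param low_hz Lower cutoff in Hz (default 5).
#' @param high_hz Upper cutoff in Hz (default 15).
#' @param order Butterworth order of each pass (default 2). The filter is
#'   applied forward and backward (zero phase), so the effective attenuation
#'   is that of twice this order.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_hz = 5, high_hz = 15, order = 2) {
  if (!(low_hz > 0 && high_hz > low_hz)) {
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (order < 1) stop("filter order must be >= 1", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order)),
            class = "filter_spec")
}

#' Band-pass filter an ECG signal
#'
#' Zero-phase Butterworth band-pass (forward-backward application via
#' [signal::filtfilt()]) with reflected padding at the boundaries, so peak
#' positions are preserved and no spurious edge transients enter the lexer.
#'
#' @param signal An [ecg_signal()].
#' @param spec A [filter_spec()]; cutoffs must lie below the Nyquist
#'   frequency `fs / 2`.
#' @return A filtered `ecg_signal` of the same length and sampling rate.
#' @export
bandpass_filter <- function(signal, spec = filter_spec()) {
  fs <- signal_fs(signal)
  if (spec$high_hz >= fs / 2) {
    stop("upper cutoff must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  n <- length(signal)
  pad <- min(n - 1L, max(3L * (spec$order + 1L) * 10L, round(fs)))
  if (n <= 2L * spec$order + 2L) {
    stop("signal too short to filter", call. = FALSE)
  }
  x <- as.numeric(signal)
  # reflect-and-invert padding keeps the extension continuous at the ends
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  set_samples(signal, y[seq(pad + 1L, pad + n)])
}

#' Centre an ECG signal at zero mean
#'
#' Subtracts the mean amplitude from every sample.
#'
#' @param signal An [ecg_signal()].
#' @return A centred `ecg_signal`.
#' @export
center_signal <- function(signal) {
  set_samples(signal, as.numeric(signal) - mean(signal))
}

#' Normalize amplitudes into \[-1, 1\]
#'
#' Divides the centred signal by its maximum absolute deviation, so every
#' sample lies in \[-1, 1\] and the extreme sample attains magnitude 1. A
#' constant signal has zero scale and is rejected rather than silently
#' divided.
#'
#' @param signal An [ecg_signal()].
#' @return A normalized `ecg_signal`.
#' @export
normalize_amplitude <- function(signal) {
  x <- as.numeric(signal) - mean(signal)
  scale <- max(abs(x))
  if (scale == 0) {
    stop("cannot normalize a constant signal (zero amplitude deviation)",
         call. = FALSE)
  }
  set_samples(signal, x / scale)
}

#' Preprocess a raw ECG for lexical analysis
#'
#' The full chain: band-pass filter, centre, normalize, in that order. The
#' output amplitude stream lies in \[-1, 1\] and is what the lexer serializes.
#'
#' @inheritParams bandpass_filter
#' @return A preprocessed `ecg_signal`.
#' @examples
#' sig <- synth_ecg(synth_config(duration_s = 10, seed = 1))$signal
#' pre <- preprocess_ecg(sig)
#' range(pre)
#' @export
preprocess_ecg <- function(signal, spec = filter_spec()) {
  signal |> bandpass_filter(spec) |> center_signal() |> normalize_amplitude()
}
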