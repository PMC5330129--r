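#' Synthetic ECG configuration
#'
#' Parameters of the fixture generator. Each beat is a sum of five
#' Gaussian-shaped deflections (P, Q, R, S, T) placed relative to the R-peak
#' time; beats are spaced by a mean RR interval with optional Gaussian
#' jitter (floored at 0.3 s so beats stay separable), plus an optional
#' sinusoidal baseline drift. Default morphology follows normal adult lead-II
#' proportions: the QRS deflections are narrow (full widths below 0.1 s) and
#' the P/T waves broad (above 0.1 s), which is exactly the amplitude-variance
#' and duration structure the detector's thresholds exploit.
#'
#' @param fs Sampling frequency in Hz (default 360, the MIT-BIH rate).
#' @param duration_s Record length in seconds.
#' @param mean_rr_s Mean RR interval in seconds (default 0.8, i.e. 75 bpm).
#' @param rr_jitter_s Standard deviation of the RR perturbation in seconds
#'   (0 gives a perfectly regular rhythm).
#' @param waves Data frame with columns `wave`, `amp` (fraction of the R
#'   amplitude), `width_s` (full wave duration; the Gaussian sd is a quarter
#'   of it) and `offset_s` (centre offset from the R peak).
#' @param baseline_amp,baseline_hz Amplitude (fraction of R) and frequency of
#'   the sinusoidal baseline drift (defaults 0.1 and 0.3 Hz).
#' @param seed Integer seed; fixes the RR jitter realization.
#' @return A `synth_config` list.
#' @export
synth_config <- function(fs = 360, duration_s = 60, mean_rr_s = 0.8,
                         rr_jitter_s = 0, waves = default_waves(),
                         baseline_amp = 0.1, baseline_hz = 0.3, seed = 1) {
  stopifnot(fs > 0, mean_rr_s > 0, rr_jitter_s >= 0,
            all(c("wave", "amp", "width_s", "offset_s") %in% names(waves)),
            all(waves$width_s > 0))
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  qrs <- waves[waves$wave %in% c("Q", "R", "S"), ]
  qrs_span <- max(qrs$offset_s + qrs$width_s / 2) -
    min(qrs$offset_s - qrs$width_s / 2)
  if (mean_rr_s <= qrs_span || 0.3 <= qrs_span) {
    stop("infeasible config: QRS deflections of adjacent beats would overlap",
         call. = FALSE)
  }
  structure(list(fs = fs, duration_s = duration_s, mean_rr_s = mean_rr_s,
                 rr_jitter_s = rr_jitter_s, waves = tibble::as_tibble(waves),
                 baseline_amp = baseline_amp, baseline_hz = baseline_hz,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_waves <- function() {
  tibble::tribble(
    ~wave, ~amp, ~width_s, ~offset_s,
    "P",   0.10,   0.110,    -0.200,
    "Q",  -0.15,   0.040,    -0.035,
    "R",   1.00,   0.050,     0.000,
    "S",  -0.45,   0.040,     0.035,
    "T",   0.25,   0.220,     0.300
  )
}

#' Generate a synthetic ECG with exact ground truth
#'
#' Places beats at jittered RR positions, sums the per-beat Gaussian
#' deflections and the baseline drift, and records the true R-peak sample
#' indices. Deterministic under the config seed; the ground-truth RR series
#' is exactly `diff(r_index) / fs`.
#'
#' @param config A [synth_config()].
#' @return A list with `signal` (raw [ecg_signal()]), `truth` (tibble with
#'   `beat`, `r_index` 0-based, `r_time_s`) and `config`.
#' @examples
#' fix <- synth_ecg(synth_config(duration_s = 10, mean_rr_s = 1, seed = 7))
#' nrow(fix$truth)
#' @export
synth_ecg <- function(config = synth_config()) {
  fs <- config$fs
  n <- round(config$duration_s * fs)
  if (n < 2L) stop("duration too short for the sampling rate", call. = FALSE)
  margin <- max(abs(config$waves$offset_s) + config$waves$width_s)
  r_times <- with_seed(config$seed, {
    ts <- margin
    out <- numeric(0)
    repeat {
      if (ts > config$duration_s - margin) break
      out <- c(out, ts)
      ts <- ts + max(0.3, stats::rnorm(1, config$mean_rr_s, config$rr_jitter_s))
    }
    out
  })
  if (!length(r_times)) {
    stop("record too short to hold a single beat", call. = FALSE)
  }
  r_idx <- round(r_times * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- config$baseline_amp * sin(2 * pi * config$baseline_hz * t)
  for (ri in r_idx / fs) {
    for (w in seq_len(nrow(config$waves))) {
      ctr <- ri + config$waves$offset_s[w]
      sdv <- config$waves$width_s[w] / 4
      lo <- max(1L, floor((ctr - 5 * sdv) * fs) + 1L)
      hi <- min(n, ceiling((ctr + 5 * sdv) * fs) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] +
        config$waves$amp[w] * exp(-((t[idx] - ctr)^2) / (2 * sdv^2))
    }
  }
  list(
    signal = ecg_signal(x, fs = fs, label = "synthetic"),
    truth = tibble::tibble(beat = seq_along(r_idx),
                           r_index = as.integer(r_idx),
                           r_time_s = r_idx / fs),
    config = config
  )
}

#' Tachycardia-regime synthetic ECG
#'
#' [synth_ecg()] preset for a fast, perfectly regular rhythm (mean RR
#' 0.46 s, about 130 bpm), the regular-beat regime; override any field via
#' `...`.
#'
#' @param ... Overrides passed to [synth_config()].
#' @return As [synth_ecg()].
#' @export
synth_tachycardia <- function(...) {
  args <- utils::modifyList(list(mean_rr_s = 0.46, rr_jitter_s = 0), list(...))
  synth_ecg(do.call(synth_config, args))
}
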