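#' Match detected beats against reference annotations
#'
#' Greedy one-to-one matching in time order: walking both sorted fiducial
#' lists, a detected beat within `tolerance_s` of the current unmatched
#' reference beat is a true positive; a detection with no admissible
#' reference is a false positive; an unmatched reference is a false
#' negative. By construction `tp + fn = length(reference)` and
#' `tp + fp = length(detected)`.
#'
#' @param detected Strictly increasing detected fiducial sample indices.
#' @param reference Strictly increasing reference fiducial sample indices.
#' @param fs Sampling frequency in Hz.
#' @param tolerance_s Matching window in seconds (default 0.15, a
#'   conventional beat-matching tolerance).
#' @return A one-row tibble with integer `tp`, `fp`, `fn`.
#' @examples
#' match_beats(c(100, 460), c(102, 462), fs = 360)
#' @export
match_beats <- function(detected, reference, fs, tolerance_s = 0.15) {
  for (v in list(detected, reference)) {
    if (length(v) > 1L && any(diff(v) <= 0)) {
      stop("fiducial lists must be strictly increasing", call. = FALSE)
    }
  }
  tol <- tolerance_s * fs
  i <- 1L; j <- 1L; tp <- 0L; fp <- 0L; fn <- 0L
  nd <- length(detected); nr <- length(reference)
  while (i <= nd && j <= nr) {
    d <- detected[i] - reference[j]
    if (abs(d) <= tol) {
      tp <- tp + 1L; i <- i + 1L; j <- j + 1L
    } else if (d < 0) {
      fp <- fp + 1L; i <- i + 1L
    } else {
      fn <- fn + 1L; j <- j + 1L
    }
  }
  fp <- fp + (nd - i + 1L)
  fn <- fn + (nr - j + 1L)
  tibble::tibble(tp = tp, fp = fp, fn = fn)
}

#' Detection-quality rates from beat counts
#'
#' Sensitivity `Se = TP/(TP+FN)`, specificity `Sp = TP/(TP+FP)` (in this
#' method's usage: the share of detections that are true beats, elsewhere
#' called positive predictivity), false detection rate `FDR = FP/(TP+FP)`
#' and false negative rate `FNR = FN/(TP+FN)`, all as percentages. `Se` and
#' `FNR` are exact algebraic complements, as are `Sp` and `FDR`.
#'
#' @param tp,fp,fn Beat counts (vectorized).
#' @return A tibble with the counts, raw percentages (`se_pct`, `sp_pct`,
#'   `fdr_pct`, `fnr_pct`) and display-rounded 2-decimal versions (`se`,
#'   `sp`, `fdr`, `fnr`, half-up rounding). A zero denominator yields `NA`
#'   for the affected rates, never 0.
#' @examples
#' confusion_rates(2272, 0, 1)
#' @export
confusion_rates <- function(tp, fp, fn) {
  stopifnot(all(tp >= 0), all(fp >= 0), all(fn >= 0))
  pos <- tp + fn
  det <- tp + fp
  se <- ifelse(pos > 0, 100 * tp / pos, NA_real_)
  sp <- ifelse(det > 0, 100 * tp / det, NA_real_)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    se_pct = se, sp_pct = sp,
    fdr_pct = ifelse(det > 0, 100 * fp / det, NA_real_),
    fnr_pct = ifelse(pos > 0, 100 * fn / pos, NA_real_),
    se = round_half_up(se), sp = round_half_up(sp),
    fdr = round_half_up(.data$fdr_pct), fnr = round_half_up(.data$fnr_pct)
  )
}

#' Evaluate a detection against reference annotations
#'
#' Convenience wrapper: [match_beats()] then [confusion_rates()].
#'
#' @param detection A `qrs_detection` from [detect_qrs()], or a vector of
#'   detected fiducial indices.
#' @inheritParams match_beats
#' @return The one-row rate tibble from [confusion_rates()].
#' @export
evaluate_detection <- function(detection, reference, fs = NULL,
                               tolerance_s = 0.15) {
  if (inherits(detection, "qrs_detection")) {
    fs <- detection$fs
    detection <- detection$r_peaks
  }
  if (is.null(fs)) stop("`fs` is required for plain fiducial vectors",
                        call. = FALSE)
  m <- match_beats(detection, reference, fs, tolerance_s)
  confusion_rates(m$tp, m$fp, m$fn)
}

#' Add white Gaussian noise at a target SNR
#'
#' Adds zero-mean Gaussian noise scaled so that
#' `10 * log10(P_signal / P_noise) = snr_db`, with both powers measured as
#' mean squared amplitude about the mean (so a DC offset does not count as
#' signal power). The realization is fixed by `seed`.
#'
#' @param signal An [ecg_signal()] with nonzero power.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @param seed Integer seed fixing the noise realization.
#' @return The noisy `ecg_signal`.
#' @examples
#' sig <- synth_ecg(synth_config(duration_s = 5, seed = 1))$signal
#' noisy <- add_noise(sig, snr_db = 20, seed = 42)
#' @export
add_noise <- function(signal, snr_db, seed) {
  x <- as.numeric(signal)
  p_sig <- mean((x - mean(x))^2)
  if (p_sig == 0) stop("cannot scale noise to a zero-power signal",
                       call. = FALSE)
  p_noise <- p_sig / 10^(snr_db / 10)
  w <- with_seed(seed, stats::rnorm(length(x), sd = sqrt(p_noise)))
  set_samples(signal, x + w)
}

#' SNR robustness sweep
#'
#' Re-runs detection on noise-corrupted copies of a signal across a grid of
#' SNR levels and seeds, scoring each run against the reference annotations.
#' Sensitivity is expected (not enforced) to degrade as SNR falls.
#'
#' @param signal A raw [ecg_signal()].
#' @param reference Reference fiducial sample indices.
#' @param snr_db Numeric vector of SNR levels in dB.
#' @param seeds Integer vector of noise seeds applied at every level.
#' @param filter,config,precision Passed to [detect_qrs()].
#' @param tolerance_s Matching window in seconds.
#' @return A tibble with one row per (snr_db, seed): the confusion counts
#'   and rates. An empty `snr_db` yields an empty tibble.
#' @export
snr_sweep <- function(signal, reference, snr_db, seeds = 1L,
                      filter = filter_spec(), config = detector_config(),
                      precision = 3, tolerance_s = 0.15) {
  grid <- tidyr::expand_grid(snr_db = as.numeric(snr_db),
                             seed = as.integer(seeds))
  purrr::pmap(grid, \(snr_db, seed) {
    det <- detect_qrs(add_noise(signal, snr_db, seed),
                      filter = filter, config = config, precision = precision)
    ev <- evaluate_detection(det, reference, tolerance_s = tolerance_s)
    dplyr::mutate(ev, snr_db = snr_db, seed = seed, .before = 1)
  }) |> purrr::list_rbind() |>
    (\(x) if (nrow(x)) x else tibble::tibble(snr_db = numeric(0),
                                             seed = integer(0)))()
}
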