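#' RR intervals from R-peak fiducials
#'
#' The RR interval is the time in seconds between two successive R peaks.
#'
#' @param r_peaks Strictly increasing fiducial sample indices.
#' @param fs Sampling frequency in Hz.
#' @return Numeric vector of RR intervals (length `length(r_peaks) - 1`;
#'   empty, with a warning, when fewer than two fiducials are given).
#' @examples
#' rr_intervals(c(0, 360, 720), fs = 360)
#' @export
rr_intervals <- function(r_peaks, fs) {
  if (length(r_peaks) < 2L) {
    warning("fewer than 2 fiducials: no RR intervals", call. = FALSE)
    return(numeric(0))
  }
  if (any(diff(r_peaks) <= 0)) {
    stop("fiducials must be strictly increasing", call. = FALSE)
  }
  diff(r_peaks) / fs
}

#' Rhythm regularity flag
#'
#' A rhythm (or QRS-duration) series is called regular when its population
#' standard deviation falls strictly below the threshold; 0.1 s is the
#' working boundary for both RR and QRS regularity.
#'
#' @param sigma Population standard deviation in seconds (>= 0).
#' @param threshold Regularity threshold (default 0.1 s). The comparison is
#'   strict: `sigma == threshold` is irregular.
#' @return `"regular"` or `"irregular"` (vectorized over `sigma`).
#' @examples
#' classify_regularity(c(0.05, 0.15))
#' @export
classify_regularity <- function(sigma, threshold = 0.1) {
  stopifnot(all(sigma >= 0))
  ifelse(sigma < threshold, "regular", "irregular")
}

#' Summarize rhythm statistics
#'
#' Means and population standard deviations of the RR-interval and
#' QRS-duration series, with regular/irregular flags at the 0.1 s threshold.
#' For a detection of `n + 1` beats there are `n` RR intervals and `n + 1`
#' QRS durations; the summary uses whatever series lengths are supplied.
#'
#' @param rr RR intervals in seconds (from [rr_intervals()]).
#' @param qrs_durations QRS complex durations in seconds.
#' @param threshold Regularity threshold in seconds (default 0.1).
#' @return A one-row tibble: `rr_mean`, `rr_sigma`, `rr_regular` (logical),
#'   `qrs_mean`, `qrs_sigma`, `qrs_regular`, `n_rr`, `n_qrs`. Empty series
#'   yield `NA` statistics with a warning.
#' @examples
#' rhythm_summary(c(0.8, 0.8, 0.8), c(0.05, 0.06, 0.05, 0.06))
#' @export
rhythm_summary <- function(rr, qrs_durations = numeric(0), threshold = 0.1) {
  if (!length(rr) && !length(qrs_durations)) {
    warning("empty RR and QRS series: degenerate summary", call. = FALSE)
  }
  stat <- function(x) {
    if (!length(x)) return(list(mean = NA_real_, sigma = NA_real_, reg = NA))
    s <- sd_pop(x)
    list(mean = mean(x), sigma = s, reg = s < threshold)
  }
  a <- stat(rr); b <- stat(qrs_durations)
  tibble::tibble(
    rr_mean = a$mean, rr_sigma = a$sigma, rr_regular = a$reg,
    qrs_mean = b$mean, qrs_sigma = b$sigma, qrs_regular = b$reg,
    n_rr = length(rr), n_qrs = length(qrs_durations)
  )
}
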