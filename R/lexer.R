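#' Serialize normalized amplitudes to decimal strings
#'
#' Every normalized sample is written as a fixed-point decimal string over the
#' alphabet `{0..9, -, .}`: an optional leading minus, exactly `precision`
#' fractional digits, no exponent. The values +1 and -1 serialize as `"1"`
#' and `"-1"`. Serialization applies round-half-even at `precision` digits
#' first, so the string view and the numeric classification can never
#' disagree.
#'
#' @param a Numeric vector of amplitudes in \[-1, 1\].
#' @param precision Number of fractional digits (default 3).
#' @return Character vector of symbol strings.
#' @examples
#' serialize_sample(c(0.3, -1, 0), precision = 2)
#' @export
serialize_sample <- function(a, precision = 3) {
  check_normalized(a)
  r <- round(a, precision)
  out <- sprintf("%.*f", precision, r)
  out[r == 1] <- "1"
  out[r == -1] <- "-1"
  # sprintf keeps a sign on negative zero; the alphabet view treats it as rest
  out
}

#' Classify a normalized amplitude as POS, NEG or REST
#'
#' Classification of the value rounded to `precision` digits: `POS` when it is
#' at least 0.1, `NEG` when at most -0.1, `REST` otherwise (magnitude below
#' 0.1). This threshold view coincides exactly with matching the serialized
#' string against the per-sample regular expressions for positive peaks,
#' negative peaks and rest samples.
#'
#' @inheritParams serialize_sample
#' @return Character vector with levels `"POS"`, `"NEG"`, `"REST"`.
#' @examples
#' classify_sample(c(0.3, -0.05, 1, -0.1))
#' @export
classify_sample <- function(a, precision = 3) {
  check_normalized(a)
  r <- round(a, precision)
  dplyr::case_when(r >= 0.1 ~ "POS", r <= -0.1 ~ "NEG", .default = "REST")
}

check_normalized <- function(a) {
  if (anyNA(a)) stop("amplitudes contain missing values", call. = FALSE)
  if (any(abs(a) > 1 + 1e-12)) {
    stop("amplitudes must lie in [-1, 1]; run preprocess_ecg() first",
         call. = FALSE)
  }
  invisible(a)
}

#' Tokenize a normalized signal into maximal same-class runs
#'
#' Partitions the sample stream into maximal runs of one class (POS, NEG or
#' REST) -- the lexemes of the signal language -- and computes each token's
#' statistics: population standard deviation `sigma`, mean amplitude, and
#' duration `k / fs` seconds for a run of `k` samples.
#'
#' @param signal A normalized [ecg_signal()] (all samples in \[-1, 1\]).
#' @param precision Serialization precision, see [classify_sample()].
#' @return A tibble with one row per token: `token` (1-based id), `class`,
#'   `start` (0-based, inclusive), `end` (exclusive), `k` (run length),
#'   `sigma`, `mean`, `duration` (seconds), and `samples` (list column with
#'   the amplitude slice). Tokens tile the signal.
#' @examples
#' sig <- ecg_signal(c(0, 0.5, 0.6, 0, -0.3, -0.2, 0.4), fs = 360)
#' tokenize(sig)
#' @export
tokenize <- function(signal, precision = 3) {
  fs <- signal_fs(signal)
  cls <- classify_sample(as.numeric(signal), precision)
  runs <- rle(cls)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths
  slices <- purrr::map2(starts + 1L, ends, \(i, j) as.numeric(signal)[i:j])
  tibble::tibble(
    token = seq_along(runs$lengths),
    class = runs$values,
    start = starts,
    end = ends,
    k = runs$lengths,
    sigma = purrr::map_dbl(slices, sd_pop),
    mean = purrr::map_dbl(slices, mean),
    duration = runs$lengths / fs,
    samples = slices
  )
}

# population standard deviation (divisor k, not k - 1)
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(sum((x - m)^2) / length(x))
}

#' Statistics of one token
#'
#' Mean amplitude, population standard deviation and duration of a run of
#' samples, as used by the detector's constraints.
#'
#' @param samples Numeric vector, the token's amplitude slice (length >= 1).
#' @param fs Sampling frequency in Hz.
#' @return A one-row tibble with `sigma`, `mean` and `duration` (seconds).
#' @examples
#' token_stats(c(0.1, 1, 0.1), fs = 360)
#' @export
token_stats <- function(samples, fs) {
  if (length(samples) < 1L) stop("empty token", call. = FALSE)
  tibble::tibble(sigma = sd_pop(samples), mean = mean(samples),
                 duration = length(samples) / fs)
}
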