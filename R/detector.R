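#' Detector configuration
#'
#' The two global thresholds separating QRS deflections from P/T waves:
#' `sigma1`, the amplitude standard-deviation threshold (dimensionless, on
#' the normalized scale), and `delta1`, the duration threshold in seconds.
#' Empirically, R and S peaks show token standard deviations above 0.2 and
#' the Q peak above 0.1, while P and T waves stay below 0.05; peak durations
#' fall below 0.1 s while P/T wave durations exceed it. The defaults
#' `sigma1 = 0.1`, `delta1 = 0.1` sit between the two populations.
#'
#' @param sigma1 Peak standard-deviation threshold (default 0.1). An R or S
#'   candidate needs token sigma above `sigma1`; a Q candidate above
#'   `sigma1 / 2`.
#' @param delta1 Peak duration threshold in seconds (default 0.1). Peak
#'   tokens must be shorter than `delta1`; rest tokens shorter than
#'   `delta1 / 2`.
#' @param strict_s Is an S peak mandatory for a beat (default `TRUE`, the
#'   grammar's printed form)? Some real morphologies lack a distinct S; the
#'   lenient mode accepts an R candidate alone but is off by default.
#' @return A `detector_config` list.
#' @export
detector_config <- function(sigma1 = 0.1, delta1 = 0.1, strict_s = TRUE) {
  if (!(sigma1 > 0 && delta1 > 0)) {
    stop("sigma1 and delta1 must be positive", call. = FALSE)
  }
  structure(list(sigma1 = sigma1, delta1 = delta1,
                 strict_s = isTRUE(strict_s)),
            class = "detector_config")
}

#' Label tokens with candidate peak roles
#'
#' Applies the sigma/duration constraints to each token:
#' * POS token with `sigma > sigma1` and `duration < delta1` -> R candidate;
#' * NEG token with `duration < delta1` -> Q candidate when
#'   `sigma > sigma1 / 2`, S candidate when `sigma > sigma1` (a deep narrow
#'   NEG token can be both; the choice is positional, made at assembly);
#' * REST token with `duration < delta1 / 2` -> rest phase;
#' * everything else (P and T waves, baseline stretches) -> `wave`.
#'
#' @param tokens A token tibble from [tokenize()].
#' @param config A [detector_config()].
#' @return The token tibble with logical columns `r_cand`, `q_cand`,
#'   `s_cand`, `rest_ok` and a summary `role` column.
#' @export
label_tokens <- function(tokens, config = detector_config()) {
  s1 <- config$sigma1; d1 <- config$delta1
  tokens |>
    dplyr::mutate(
      r_cand = .data$class == "POS" & .data$sigma > s1 & .data$duration < d1,
      q_cand = .data$class == "NEG" & .data$sigma > s1 / 2 & .data$duration < d1,
      s_cand = .data$class == "NEG" & .data$sigma > s1 & .data$duration < d1,
      rest_ok = .data$class == "REST" & .data$duration < d1 / 2,
      role = dplyr::case_when(
        r_cand ~ "R-candidate",
        s_cand & q_cand ~ "QS-candidate",
        q_cand ~ "Q-candidate",
        rest_ok ~ "rest",
        .default = "wave"
      )
    )
}

#' Assemble QRS complexes from labeled tokens
#'
#' Greedy left-to-right scan emitting non-overlapping matches of
#' `{Q}? {rest}? {R} {rest}? {S}`: for each unconsumed R candidate, an
#' immediately preceding rest and/or Q candidate is attached, then an
#' optional rest and the mandatory S candidate are consumed on the right.
#' Each token is used at most once; a NEG token that could close one beat or
#' open the next is taken as the S of the left beat. In strict mode an R with
#' no qualifying S (allowing one rest in between) yields no beat.
#'
#' @param labeled Output of [label_tokens()].
#' @param config A [detector_config()].
#' @param fs Sampling frequency in Hz.
#' @return A tibble with one row per complex: token row ids (`q_token`,
#'   `rest1_token`, `r_token`, `rest2_token`, `s_token`, `NA` where absent),
#'   `onset`/`offset` (0-based sample indices, offset exclusive) and
#'   `duration` in seconds.
#' @export
assemble_qrs <- function(labeled, config = detector_config(), fs) {
  n <- nrow(labeled)
  consumed <- logical(n)
  beats <- list()
  free <- function(j) j >= 1L && j <= n && !consumed[j]
  for (ri in which(labeled$r_cand)) {
    if (consumed[ri]) next
    # optional rest / Q to the left
    j <- ri - 1L
    rest1 <- NA_integer_; q <- NA_integer_
    if (free(j) && labeled$rest_ok[j]) { rest1 <- j; j <- j - 1L }
    if (free(j) && labeled$q_cand[j]) q <- j
    # optional rest then S to the right
    j <- ri + 1L
    rest2 <- NA_integer_; s <- NA_integer_
    if (free(j) && labeled$rest_ok[j]) { rest2 <- j; j <- j + 1L }
    if (free(j) && labeled$s_cand[j]) s <- j
    if (is.na(s)) {
      if (config$strict_s) { consumed[ri] <- TRUE; next }
      rest2 <- NA_integer_  # lenient beat is Q?-rest?-R only
    }
    parts <- c(q, rest1, ri, rest2, s)
    consumed[parts[!is.na(parts)]] <- TRUE
    first <- min(parts, na.rm = TRUE); last <- max(parts, na.rm = TRUE)
    beats[[length(beats) + 1L]] <- tibble::tibble(
      q_token = q, rest1_token = rest1, r_token = ri,
      rest2_token = rest2, s_token = s,
      onset = labeled$start[first], offset = labeled$end[last]
    )
  }
  out <- if (length(beats)) dplyr::bind_rows(beats) else tibble::tibble(
    q_token = integer(0), rest1_token = integer(0), r_token = integer(0),
    rest2_token = integer(0), s_token = integer(0),
    onset = integer(0), offset = integer(0)
  )
  dplyr::mutate(out, duration = (.data$offset - .data$onset) / fs)
}

#' Locate the R-peak fiducial within a beat
#'
#' The fiducial is the index of the maximum amplitude inside the beat's R
#' token; ties break to the earliest index.
#'
#' @param r_start 0-based start index of the R token.
#' @param r_samples Amplitude slice of the R token.
#' @return 0-based sample index of the R peak.
#' @export
locate_r_peak <- function(r_start, r_samples) {
  r_start + which.max(r_samples) - 1L
}

#' Detect QRS complexes in a raw ECG
#'
#' Runs the full chain: preprocess (band-pass, centre, normalize), tokenize,
#' compute token statistics, label candidates against the sigma/duration
#' thresholds, assemble complexes by the grammar, and locate R-peak
#' fiducials. Deterministic for fixed input and configuration.
#'
#' @param signal A raw [ecg_signal()].
#' @param filter A [filter_spec()].
#' @param config A [detector_config()].
#' @param precision Serialization precision for the lexer (default 3).
#' @return A `qrs_detection` object with components `beats` (tibble: one row
#'   per complex with onset/offset/r_peak in samples and seconds), `r_peaks`
#'   (0-based fiducial indices), `tokens` (the labeled token tibble),
#'   `signal` (the preprocessed signal), `config`, `filter` and `label`.
#'   Use [tidy()] for the beat table and [glance()] for a one-row rhythm
#'   summary.
#' @examples
#' fix <- synth_ecg(synth_config(duration_s = 20, seed = 2))
#' det <- detect_qrs(fix$signal)
#' det
#' glance(det)
#' @export
detect_qrs <- function(signal, filter = filter_spec(),
                       config = detector_config(), precision = 3) {
  fs <- signal_fs(signal)
  pre <- preprocess_ecg(signal, filter)
  labeled <- label_tokens(tokenize(pre, precision), config)
  beats <- assemble_qrs(labeled, config, fs)
  r_peaks <- purrr::map_int(beats$r_token, \(ri) {
    locate_r_peak(labeled$start[ri], labeled$samples[[ri]])
  })
  beats <- beats |>
    dplyr::mutate(
      beat = dplyr::row_number(), r_peak = r_peaks,
      onset_s = .data$onset / fs, offset_s = .data$offset / fs,
      r_peak_s = .data$r_peak / fs, .before = 1
    )
  structure(list(beats = beats, r_peaks = r_peaks, tokens = labeled,
                 signal = pre, config = config, filter = filter,
                 precision = precision, fs = fs, label = signal_label(signal)),
            class = "qrs_detection")
}

#' @export
print.qrs_detection <- function(x, ...) {
  cat(sprintf("<qrs_detection> %d beats in %.1f s @ %g Hz%s\n",
              nrow(x$beats), length(x$signal) / x$fs, x$fs,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  if (nrow(x$beats) >= 2) {
    g <- glance(x)
    cat(sprintf("  mean RR %.3f s (sigma %.3f, %s); mean QRS %.3f s (sigma %.3f, %s)\n",
                g$rr_mean, g$rr_sigma,
                ifelse(g$rr_regular, "regular", "irregular"),
                g$qrs_mean, g$qrs_sigma,
                ifelse(g$qrs_regular, "regular", "irregular")))
  }
  invisible(x)
}

#' @rdname detect_qrs
#' @param x A `qrs_detection` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.qrs_detection <- function(x, ...) {
  dplyr::select(x$beats, "beat", "onset", "offset", "r_peak",
                "onset_s", "offset_s", "r_peak_s", "duration",
                "q_token", "r_token", "s_token")
}

#' @rdname detect_qrs
#' @exportS3Method generics::glance
glance.qrs_detection <- function(x, ...) {
  summ <- rhythm_summary(rr_intervals(x$r_peaks, x$fs), x$beats$duration)
  dplyr::mutate(summ, n_beats = nrow(x$beats), label = x$label, .before = 1)
}
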