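#' Read a single-column signal CSV
#'
#' One amplitude per row; an optional non-numeric header line and blank
#' lines are ignored. Parse failures report the offending line number.
#'
#' @param path File path.
#' @param fs Sampling frequency in Hz (not stored in the CSV).
#' @param label Record label (defaults to the file name).
#' @return An [ecg_signal()].
#' @export
read_signal_csv <- function(path, fs, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- which(nzchar(lines))
  if (!length(keep)) stop("empty signal file: ", path, call. = FALSE)
  vals <- suppressWarnings(as.numeric(lines[keep]))
  bad <- which(is.na(vals))
  if (length(bad) && bad[1] == 1L) {  # header line
    vals <- vals[-1]; keep <- keep[-1]; bad <- which(is.na(vals))
  }
  if (length(bad)) {
    stop("non-numeric value at line ", keep[bad[1]], " of ", path,
         call. = FALSE)
  }
  if (!length(vals)) stop("no samples in ", path, call. = FALSE)
  ecg_signal(vals, fs = fs, label = label)
}

#' Write a signal to a single-column CSV
#'
#' @param signal An [ecg_signal()].
#' @param path Output path (written atomically).
#' @return The path, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  write_atomic(path, \(tmp) {
    writeLines(c("amplitude", format(as.numeric(signal), digits = 15,
                                     scientific = FALSE, trim = TRUE)), tmp)
  })
}

#' Read beat annotations from CSV
#'
#' Expected columns `sample_index` (0-based) and `label`; a bare
#' single-column file of indices is also accepted.
#'
#' @param path File path.
#' @return A tibble with `sample_index` (integer, strictly increasing) and
#'   `label`.
#' @export
read_annotations_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, strip.white = TRUE)
  if (!"sample_index" %in% names(df)) {
    if (ncol(df) >= 1L) names(df)[1] <- "sample_index"
  }
  if (!"label" %in% names(df)) df$label <- "N"
  idx <- as.integer(df$sample_index)
  if (anyNA(idx)) stop("non-integer sample_index in ", path, call. = FALSE)
  if (is.unsorted(idx, strictly = TRUE)) {
    stop("annotation indices must be strictly increasing", call. = FALSE)
  }
  tibble::tibble(sample_index = idx, label = as.character(df$label))
}

#' Write beat annotations to CSV
#'
#' @param sample_index Integer vector of 0-based beat indices, or a tibble
#'   with columns `sample_index` and `label`.
#' @param path Output path (written atomically).
#' @param label Beat label used when `sample_index` is a bare vector.
#' @return The path, invisibly.
#' @export
write_annotations_csv <- function(sample_index, path, label = "N") {
  ann <- if (is.data.frame(sample_index)) sample_index else
    tibble::tibble(sample_index = as.integer(sample_index), label = label)
  write_atomic(path, \(tmp) {
    utils::write.csv(ann, tmp, row.names = FALSE, quote = FALSE)
  })
}

#' Write a detection report as JSON
#'
#' A versioned JSON document with the configuration echo, the beat table
#' (onset/offset/R peak in both samples and seconds), the rhythm summary,
#' and the evaluation block (or `null` when no reference was supplied).
#' Percentages appear display-rounded to 2 decimals with the raw values kept
#' under `raw`.
#'
#' @param detection A `qrs_detection` from [detect_qrs()].
#' @param path Output path (written atomically).
#' @param evaluation Optional one-row tibble from [evaluate_detection()].
#' @return The path, invisibly.
#' @export
write_report <- function(detection, path, evaluation = NULL) {
  stopifnot(inherits(detection, "qrs_detection"))
  summ <- glance(detection)
  eval_block <- if (is.null(evaluation)) NULL else list(
    tp = evaluation$tp, fp = evaluation$fp, fn = evaluation$fn,
    se = evaluation$se, sp = evaluation$sp,
    fdr = evaluation$fdr, fnr = evaluation$fnr,
    raw = list(se_pct = evaluation$se_pct, sp_pct = evaluation$sp_pct,
               fdr_pct = evaluation$fdr_pct, fnr_pct = evaluation$fnr_pct)
  )
  report <- list(
    schema = "qrslex-report/1",
    label = detection$label,
    fs = detection$fs,
    config = list(sigma1 = detection$config$sigma1,
                  delta1 = detection$config$delta1,
                  strict_s = detection$config$strict_s,
                  filter = unclass(detection$filter),
                  precision = detection$precision),
    n_beats = nrow(detection$beats),
    beats = tidy(detection),
    rhythm = as.list(summ[setdiff(names(summ), c("label"))]),
    evaluation = eval_block
  )
  write_atomic(path, \(tmp) {
    jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  })
}

#' @rdname write_report
#' @return `read_report()`: the parsed report as a list, with `beats` as a
#'   tibble.
#' @export
read_report <- function(path) {
  rep <- jsonlite::fromJSON(path)
  if (!is.null(rep$beats) && length(rep$beats)) {
    rep$beats <- tibble::as_tibble(rep$beats)
  }
  rep
}

# ---- WFDB (MIT-BIH style) reading ------------------------------------------

parse_wfdb_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  name <- sub("/.*", "", rec[1])
  n_sig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[3])) else 250
  n_samp <- if (length(rec) >= 4) as.numeric(rec[4]) else NA_real_
  sigs <- purrr::map(seq_len(n_sig), \(i) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("^([-0-9.]+).*", "\\1", gain_field))
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gain_field))
    } else NA_real_
    adc_zero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    list(file = f[1], format = sub("x.*|:.*|\\+.*", "", f[2]), gain = gain,
         baseline = if (is.na(baseline)) adc_zero else baseline)
  })
  list(name = name, n_sig = n_sig, fs = fs, n_samp = n_samp, signals = sigs)
}

read_dat_samples <- function(dat_path, format, n_sig, n_samp) {
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  if (format == "212") {
    nb <- (length(raw) %/% 3L) * 3L
    b <- as.integer(raw[seq_len(nb)])
    b0 <- b[seq(1, nb, 3)]; b1 <- b[seq(2, nb, 3)]; b2 <- b[seq(3, nb, 3)]
    s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8L)
    s2 <- b2 + bitwShiftL(bitwAnd(b1, 0xF0L), 4L)
    s1 <- ifelse(s1 >= 2048L, s1 - 4096L, s1)
    s2 <- ifelse(s2 >= 2048L, s2 - 4096L, s2)
    adc <- as.vector(rbind(s1, s2))
  } else if (format == "16") {
    adc <- readBin(dat_path, "integer", size = 2, signed = TRUE,
                   endian = "little",
                   n = file.size(dat_path) %/% 2L)
  } else {
    stop("unsupported WFDB signal format: ", format, call. = FALSE)
  }
  mat <- matrix(adc[seq_len((length(adc) %/% n_sig) * n_sig)], nrow = n_sig)
  if (is.finite(n_samp) && n_samp > 0) {
    mat <- mat[, seq_len(min(ncol(mat), n_samp)), drop = FALSE]
  }
  mat
}

# MIT annotation codes that denote beats (normal, BBB, ectopic, escape,
# paced, fusion and unclassifiable beats); non-beat codes are dropped
wfdb_beat_codes <- c(1:13, 34, 35, 38)

read_atr_annotations <- function(atr_path) {
  raw <- as.integer(readBin(atr_path, "raw", n = file.size(atr_path)))
  i <- 1L; time <- 0; out_idx <- integer(0); out_code <- integer(0)
  nb <- length(raw)
  while (i + 1L <= nb) {
    a <- raw[i] + 256L * raw[i + 1L]
    i <- i + 2L
    code <- a %/% 1024L
    interval <- a %% 1024L
    if (code == 0L && interval == 0L) break
    if (code == 59L) {  # SKIP: 4-byte interval, high 16-bit word first
      if (i + 3L > nb) break
      w1 <- raw[i] + 256L * raw[i + 1L]
      w2 <- raw[i + 2L] + 256L * raw[i + 3L]
      i <- i + 4L
      time <- time + w1 * 65536 + w2
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM / SUB / CHN modifiers: no time advance
    } else if (code == 63L) {  # AUX: `interval` bytes of payload, padded
      i <- i + interval + interval %% 2L
    } else {
      time <- time + interval
      out_idx <- c(out_idx, time)
      out_code <- c(out_code, code)
    }
  }
  tibble::tibble(sample_index = as.integer(out_idx), code = out_code)
}

#' Read a WFDB (MIT-BIH style) record
#'
#' Minimal reader for the `.hea`/`.dat`(/`.atr`) triplet: the header gives
#' the sampling frequency, gain and baseline; signal formats 212 (packed
#' 12-bit, the MIT-BIH format) and 16 (little-endian int16) are supported;
#' amplitudes are converted to physical units as `(adc - baseline) / gain`.
#' The first channel is extracted. Beat annotations in a sibling `.atr`
#' file, when present, are decoded and non-beat codes dropped.
#'
#' @param record_path Path to the record without extension (e.g.
#'   `"mitdb/100"`).
#' @return A list with `signal` (an [ecg_signal()]) and `annotations` (a
#'   tibble with `sample_index` and `label`, or `NULL` when no `.atr` file
#'   exists).
#' @export
read_wfdb_record <- function(record_path) {
  hea <- paste0(record_path, ".hea")
  if (!file.exists(hea)) stop("no such WFDB header: ", hea, call. = FALSE)
  hdr <- parse_wfdb_header(hea)
  dat <- file.path(dirname(record_path), hdr$signals[[1]]$file)
  if (!file.exists(dat)) stop("missing WFDB signal file: ", dat, call. = FALSE)
  mat <- read_dat_samples(dat, hdr$signals[[1]]$format, hdr$n_sig, hdr$n_samp)
  ch1 <- (mat[1, ] - hdr$signals[[1]]$baseline) / hdr$signals[[1]]$gain
  sig <- ecg_signal(ch1, fs = hdr$fs, label = hdr$name)
  atr <- paste0(record_path, ".atr")
  ann <- NULL
  if (file.exists(atr)) {
    all_ann <- read_atr_annotations(atr)
    beats <- all_ann[all_ann$code %in% wfdb_beat_codes, ]
    ann <- tibble::tibble(sample_index = beats$sample_index, label = "N")
  }
  list(signal = sig, annotations = ann)
}
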