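# shared fixture builders; everything is generated in code at test time

fixture_clean <- function(duration_s = 30, mean_rr_s = 1, jitter = 0,
                          seed = 3, ...) {
  synth_ecg(synth_config(duration_s = duration_s, mean_rr_s = mean_rr_s,
                         rr_jitter_s = jitter, seed = seed, ...))
}

# pure sinusoid as an ecg_signal, for filter frequency-response checks
sinusoid <- function(freq_hz, fs = 360, duration_s = 10, amp = 1) {
  t <- seq(0, duration_s, by = 1 / fs)
  ecg_signal(amp * sin(2 * pi * freq_hz * t), fs = fs)
}

rms <- function(x) sqrt(mean(as.numeric(x)^2))

# hand-build a labeled-token tibble for assembly tests; each row is
# (class, sigma, duration); starts/ends are synthesized contiguously
labeled_fixture <- function(classes, sigmas, durations, fs = 360,
                            config = detector_config()) {
  k <- pmax(1L, round(durations * fs))
  end <- cumsum(k)
  start <- end - k
  tok <- tibble::tibble(
    token = seq_along(classes), class = classes, start = start, end = end,
    k = k, sigma = sigmas, mean = ifelse(classes == "NEG", -0.3,
                                         ifelse(classes == "POS", 0.5, 0)),
    duration = k / fs,
    samples = purrr::map2(k, .data$mean, \(n, m) rep(m, n))
  )
  label_tokens(tok, config)
}

# random symbol strings over the serialization alphabet: half uniform, half
# stitched from plausible fragments so accepting strings actually occur
random_sigma_strings <- function(n, seed, max_len = 12) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    alpha <- c(as.character(0:9), "-", ".")
    frag <- c("0.", "-0.", "1", "-1", "0.0", "0.5", "-0.4", "0.00", "0.30")
    uni <- replicate(n %/% 2, paste(sample(alpha, sample(0:max_len, 1),
                                           replace = TRUE), collapse = ""))
    stitched <- replicate(n - n %/% 2,
                          paste(sample(frag, sample(1:5, 1), replace = TRUE),
                                collapse = ""))
    c(uni, stitched)
  })
}

machine_accepts <- function(machine, inputs) {
  vapply(inputs, \(s) run_automaton(machine, s)$accepted, logical(1),
         USE.NAMES = FALSE)
}

# write a tiny WFDB record (format 212, one channel, gain 200, baseline
# 1024) plus a .atr beat-annotation file; returns the record path sans ext
write_wfdb_fixture <- function(dir, samples, r_index, fs = 360,
                               name = "synt01") {
  gain <- 200; base <- 1024
  adc <- pmin(2047, pmax(-2048, round(samples * gain) + base))
  if (length(adc) %% 2L) adc <- c(adc, adc[length(adc)])
  v <- ifelse(adc < 0, adc + 4096, adc)
  i1 <- seq(1, length(v), by = 2); i2 <- i1 + 1
  bytes <- as.raw(rbind(v[i1] %% 256,
                        (v[i1] %/% 256) + 16 * (v[i2] %/% 256),
                        v[i2] %% 256))
  writeBin(as.vector(bytes), file.path(dir, paste0(name, ".dat")))
  writeLines(c(
    sprintf("%s 1 %d %d", name, fs, length(samples)),
    sprintf("%s.dat 212 %d(%d)/mV 11 %d 0 0 0 MLII", name, gain, base, base)
  ), file.path(dir, paste0(name, ".hea")))
  # .atr: NORMAL (code 1) beats as code<<10 | interval words, EOF word 0
  stopifnot(all(diff(c(0, r_index)) < 1024))
  words <- bitwShiftL(1L, 10L) + as.integer(diff(c(0L, r_index)))
  atr <- as.raw(rbind(words %% 256L, words %/% 256L))
  writeBin(c(as.vector(atr), as.raw(c(0, 0))),
           file.path(dir, paste0(name, ".atr")))
  file.path(dir, name)
}
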