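test_that("beat matching is greedy, one-to-one and in time order", {
  m <- match_beats(c(100, 460), c(102, 462), fs = 360, tolerance_s = 0.15)
  expect_equal(unlist(m), c(tp = 2L, fp = 0L, fn = 0L))
  m2 <- match_beats(100, c(100, 460), fs = 360)
  expect_equal(unlist(m2), c(tp = 1L, fp = 0L, fn = 1L))
  m3 <- match_beats(c(100, 104), 100, fs = 360)
  expect_equal(unlist(m3), c(tp = 1L, fp = 1L, fn = 0L))
  expect_error(match_beats(c(5, 2), 1, fs = 360), "increasing")
})

test_that("matching respects the bound tp <= min(detected, reference)", {
  for (seed in 1:6) {
    set.seed(seed)
    det <- sort(sample(1:5000, 30))
    ref <- sort(sample(1:5000, 25))
    m <- match_beats(det, ref, fs = 360, tolerance_s = 0.1)
    expect_lte(m$tp, min(length(det), length(ref)))
    expect_equal(m$tp + m$fp, length(det))
    expect_equal(m$tp + m$fn, length(ref))
  }
  # tolerance 0 keeps only exact coincidences
  m0 <- match_beats(c(10, 20, 30), c(10, 21, 30), fs = 360, tolerance_s = 0)
  expect_equal(m0$tp, 2L)
})

test_that("rates follow the defining formulas with exact complementarity", {
  r <- confusion_rates(123, 7, 11)
  expect_equal(r$se_pct, 100 * 123 / 134)
  expect_equal(r$sp_pct, 100 * 123 / 130)
  expect_equal(r$se_pct + r$fnr_pct, 100)
  expect_equal(r$sp_pct + r$fdr_pct, 100)
  nodet <- confusion_rates(0, 0, 5)
  expect_true(is.na(nodet$sp_pct))  # undefined, never reported as 0
  expect_equal(nodet$se_pct, 0)
})

test_that("noise injection hits the target SNR and is reproducible", {
  fix <- fixture_clean(duration_s = 30, mean_rr_s = 0.8, seed = 9)
  sig <- fix$signal
  measured_snr <- function(noisy, clean) {
    w <- as.numeric(noisy) - as.numeric(clean)
    x <- as.numeric(clean) - mean(clean)
    10 * log10(mean(x^2) / mean(w^2))
  }
  n20 <- add_noise(sig, snr_db = 20, seed = 101)
  expect_lt(abs(measured_snr(n20, sig) - 20), 0.5)
  # longer record: calibration tightens below 0.1 dB
  long <- fixture_clean(duration_s = 300, mean_rr_s = 0.8, seed = 9)$signal
  expect_lt(abs(measured_snr(add_noise(long, 10, seed = 5), long) - 10), 0.1)
  expect_identical(as.numeric(add_noise(sig, 20, seed = 7)),
                   as.numeric(add_noise(sig, 20, seed = 7)))
  expect_error(add_noise(ecg_signal(c(1, 1, 1), 360), 20, 1), "zero-power")
})

test_that("near-noiseless injection leaves the detection unchanged", {
  fix <- fixture_clean(duration_s = 30, mean_rr_s = 0.8, seed = 10)
  det_clean <- detect_qrs(fix$signal)
  det_90 <- detect_qrs(add_noise(fix$signal, snr_db = 90, seed = 1))
  m <- match_beats(det_90$r_peaks, det_clean$r_peaks, fs = 360,
                   tolerance_s = 0.05)
  expect_equal(m$fp, 0L)
  expect_equal(m$fn, 0L)
})

test_that("the SNR sweep returns one scored row per level and seed", {
  fix <- fixture_clean(duration_s = 20, mean_rr_s = 0.8, seed = 12)
  sw <- snr_sweep(fix$signal, fix$truth$r_index, snr_db = c(60, 20),
                  seeds = 1:2, tolerance_s = 0.05)
  expect_equal(nrow(sw), 4L)
  expect_true(all(c("snr_db", "seed", "tp", "se_pct") %in% names(sw)))
  empty <- snr_sweep(fix$signal, fix$truth$r_index, snr_db = numeric(0))
  expect_equal(nrow(empty), 0L)
})
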