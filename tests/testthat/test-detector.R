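test_that("token labeling applies the sigma and duration constraints", {
  lab <- labeled_fixture(
    classes = c("POS", "NEG", "NEG", "REST", "REST", "POS"),
    sigmas = c(0.42, 0.06, 0.25, 0, 0, 0.42),
    durations = c(0.008, 0.02, 0.02, 0.02, 0.2, 0.15)
  )
  expect_true(lab$r_cand[1])
  expect_equal(lab$role[1], "R-candidate")
  # sigma 0.06: above sigma1/2 but not sigma1 -> Q only
  expect_true(lab$q_cand[2]); expect_false(lab$s_cand[2])
  expect_equal(lab$role[2], "Q-candidate")
  # deep narrow NEG qualifies for both roles
  expect_true(lab$q_cand[3] && lab$s_cand[3])
  expect_equal(lab$role[3], "QS-candidate")
  expect_true(lab$rest_ok[4])
  expect_false(lab$rest_ok[5])      # 0.2 s fails delta1/2
  expect_equal(lab$role[5], "wave")
  expect_false(lab$r_cand[6])       # 0.15 s fails delta1
})

test_that("assembly emits complexes per the grammar", {
  fs <- 360
  # Q rest R rest S -> one beat with all five parts
  lab <- labeled_fixture(c("NEG", "REST", "POS", "REST", "NEG"),
                         c(0.2, 0, 0.4, 0, 0.3),
                         c(0.02, 0.01, 0.02, 0.01, 0.02))
  beats <- assemble_qrs(lab, detector_config(), fs)
  expect_equal(nrow(beats), 1L)
  expect_equal(beats$q_token, 1L)
  expect_equal(beats$s_token, 5L)
  expect_equal(beats$onset, lab$start[1])
  expect_equal(beats$offset, lab$end[5])
  expect_equal(beats$duration, (lab$end[5] - lab$start[1]) / fs)

  # R S alone -> one beat, Q absent
  lab2 <- labeled_fixture(c("POS", "NEG"), c(0.4, 0.3), c(0.02, 0.02))
  beats2 <- assemble_qrs(lab2, detector_config(), fs)
  expect_equal(nrow(beats2), 1L)
  expect_true(is.na(beats2$q_token))

  # R alone: strict mode drops it, lenient mode keeps it
  lab3 <- labeled_fixture("POS", 0.4, 0.02)
  expect_equal(nrow(assemble_qrs(lab3, detector_config(), fs)), 0L)
  lenient <- assemble_qrs(lab3, detector_config(strict_s = FALSE), fs)
  expect_equal(nrow(lenient), 1L)
})

test_that("a NEG token between two R candidates closes the left beat", {
  lab <- labeled_fixture(c("POS", "NEG", "POS", "NEG"),
                         c(0.4, 0.3, 0.4, 0.3),
                         c(0.02, 0.02, 0.02, 0.02))
  beats <- assemble_qrs(lab, detector_config(), 360)
  expect_equal(nrow(beats), 2L)
  expect_equal(beats$s_token, c(2L, 4L))
  expect_true(all(is.na(beats$q_token)))  # token 2 is S of beat 1, not Q of 2
})

test_that("the R-peak fiducial is the token argmax with earliest-tie rule", {
  expect_equal(locate_r_peak(100L, c(0.2, 0.9, 0.3)), 101L)
  expect_equal(locate_r_peak(100L, c(0.9, 0.9)), 100L)
  expect_equal(locate_r_peak(42L, 0.7), 42L)
})

test_that("detection on a clean fixture recovers every ground-truth beat", {
  fix <- fixture_clean(duration_s = 30, mean_rr_s = 1, seed = 3)
  det <- detect_qrs(fix$signal)
  expect_lte(abs(nrow(det$beats) - 30), 1)
  ev <- evaluate_detection(det, fix$truth$r_index, tolerance_s = 0.05)
  expect_equal(ev$se_pct, 100)
  expect_equal(ev$fp, 0L)
  expect_error(detect_qrs(ecg_signal(rep(0, 4000), fs = 360)), "constant")
})

test_that("broad T waves are rejected by the duration constraint", {
  waves <- default_waves()
  waves$amp[waves$wave == "T"] <- 0.3
  waves$width_s[waves$wave == "T"] <- 0.16
  fix <- synth_ecg(synth_config(duration_s = 30, mean_rr_s = 1, seed = 4,
                                waves = waves))
  det <- detect_qrs(fix$signal)
  ev <- evaluate_detection(det, fix$truth$r_index, tolerance_s = 0.05)
  expect_equal(ev$fp, 0L)          # no beats fabricated from T waves
  expect_equal(ev$se_pct, 100)
})

test_that("beats never overlap and are strictly increasing", {
  for (seed in c(11, 12, 13)) {
    fix <- fixture_clean(duration_s = 60, mean_rr_s = 0.7, jitter = 0.08,
                         seed = seed)
    det <- detect_qrs(fix$signal)
    b <- det$beats
    expect_true(all(diff(b$r_peak) > 0))
    expect_true(all(b$onset[-1] >= b$offset[-nrow(b)]))
    expect_true(all(b$onset <= b$r_peak & b$r_peak < b$offset))
  }
})

test_that("raising sigma1 never increases the number of detected beats", {
  fix <- fixture_clean(duration_s = 60, mean_rr_s = 0.8, jitter = 0.05,
                       seed = 21)
  counts <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.45),
                   \(s1) nrow(detect_qrs(fix$signal,
                                         config = detector_config(sigma1 = s1))$beats),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("each emitted beat serializes to a string the QRS machine accepts", {
  fix <- fixture_clean(duration_s = 20, mean_rr_s = 0.9, seed = 6)
  det <- detect_qrs(fix$signal)
  m <- build_qrs_machine()
  expect_gt(nrow(det$beats), 10)
  for (i in seq_len(nrow(det$beats))) {
    parts <- unlist(det$beats[i, c("q_token", "rest1_token", "r_token",
                                   "rest2_token", "s_token")])
    parts <- parts[!is.na(parts)]
    s <- paste(unlist(lapply(det$tokens$samples[parts], serialize_sample)),
               collapse = "")
    expect_true(run_automaton(m, s)$accepted, info = paste("beat", i))
  }
})

test_that("tidy and glance expose the beat table and rhythm summary", {
  fix <- fixture_clean(duration_s = 30, mean_rr_s = 1, seed = 3)
  det <- detect_qrs(fix$signal)
  td <- tidy(det)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("beat", "onset", "offset", "r_peak", "duration") %in%
                    names(td)))
  g <- glance(det)
  expect_equal(g$n_beats, nrow(td))
  expect_equal(g$rr_mean, 1, tolerance = 1e-3)
  expect_true(g$rr_regular)
})
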