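test_that("the positive-peak machine accepts serialized R samples", {
  m <- build_positive_peak_machine()
  expect_true(run_automaton(m, "0.5")$accepted)
  expect_true(run_automaton(m, "1")$accepted)
  expect_false(run_automaton(m, "0.05")$accepted)
  expect_true(run_automaton(m, "0.30.4")$accepted)  # '+' via epsilon loop
  expect_true(run_automaton(m, "11")$accepted)
  expect_false(run_automaton(m, "")$accepted)       # '+' needs >= 1
  expect_error(run_automaton(m, "0.5x"), "alphabet")
})

test_that("the negative-peak machine accepts serialized Q/S samples", {
  m <- build_negative_peak_machine()
  expect_true(run_automaton(m, "-0.30")$accepted)
  expect_true(run_automaton(m, "-1")$accepted)
  expect_false(run_automaton(m, "0.30")$accepted)
  expect_true(run_automaton(m, "-0.3-1")$accepted)
  expect_false(run_automaton(m, "-")$accepted)
})

test_that("the rest machine accepts near-isoelectric runs", {
  m <- build_rest_machine()
  expect_true(run_automaton(m, "0.00")$accepted)
  expect_true(run_automaton(m, "-0.05")$accepted)
  expect_false(run_automaton(m, "0.5")$accepted)
  expect_true(run_automaton(m, "0.00.01")$accepted)  # repetition
  expect_false(run_automaton(m, "0.")$accepted)
})

test_that("the composite machine accepts whole serialized complexes", {
  m <- build_qrs_machine()
  full <- paste0(serialize_sample(c(-0.3, 0.02, 0.9, 0.01, -0.4)),
                 collapse = "")
  expect_true(run_automaton(m, full)$accepted)
  expect_true(run_automaton(m, "0.9-0.4")$accepted)   # Q and rests absent
  expect_false(run_automaton(m, "0.9")$accepted)      # S mandatory
  expect_false(run_automaton(m, "")$accepted)
  expect_false(matches_pattern("QRS", ""))
  # leading rest with Q absent is part of the language
  expect_true(run_automaton(m, "0.000.9-0.4")$accepted)
  expect_true(matches_pattern("QRS", "0.000.9-0.4"))
})

test_that("machine runs are deterministic and report consumed prefixes", {
  m <- build_positive_peak_machine()
  r1 <- run_automaton(m, "0.30.4")
  r2 <- run_automaton(m, "0.30.4")
  expect_identical(r1, r2)
  r <- run_automaton(m, "0.3-")
  expect_false(r$accepted)
  expect_equal(r$consumed, 3L)
  expect_lte(run_automaton(m, "0.05")$consumed, 4L)
})

test_that("each machine's language equals its regular expression", {
  machines <- list(R = build_positive_peak_machine(),
                   Qneg = build_negative_peak_machine(),
                   Sneg = build_negative_peak_machine(),
                   rest = build_rest_machine(),
                   QRS = build_qrs_machine())
  ser <- serialize_sample(seq(-1, 1, by = 0.01))
  inputs <- c(ser, random_sigma_strings(2000, seed = 99))
  for (nm in names(machines)) {
    expect_equal(machine_accepts(machines[[nm]], inputs),
                 matches_pattern(nm, inputs),
                 info = nm)
  }
})

test_that("the composite machine agrees with brute-force segmentation", {
  # accepted iff the string splits as Q? rest? R rest? S with each part
  # matching its own pattern; enumerate all cut points on short strings
  segments_ok <- function(s) {
    n <- nchar(s)
    # precompute pattern matches for every substring [i+1, j] (0 <= i <= j <= n)
    sub_ok <- function(pat, allow_empty) {
      m <- matrix(FALSE, n + 1, n + 1)
      for (i in 0:n) for (j in i:n) {
        piece <- substr(s, i + 1, j)
        m[i + 1, j + 1] <- if (i == j) allow_empty else
          matches_pattern(pat, piece)
      }
      m
    }
    q <- sub_ok("Qneg", TRUE); rest <- sub_ok("rest", TRUE)
    r <- sub_ok("R", FALSE); sneg <- sub_ok("Sneg", FALSE)
    # all non-decreasing 4-tuples of cut points (segments may be empty)
    for (b1 in 0:n) for (b2 in b1:n) for (b3 in b2:n) for (b4 in b3:n) {
      if (q[1, b1 + 1] && rest[b1 + 1, b2 + 1] && r[b2 + 1, b3 + 1] &&
          rest[b3 + 1, b4 + 1] && sneg[b4 + 1, n + 1]) {
        return(TRUE)
      }
    }
    FALSE
  }
  m <- build_qrs_machine()
  set.seed(5)
  frag <- c("0.", "-0.", "1", "-1", "0.0", "0.5", "-0.4", "0.00")
  shorts <- unique(replicate(300, paste(sample(frag, sample(1:4, 1),
                                               replace = TRUE),
                                        collapse = "")))
  shorts <- shorts[nchar(shorts) <= 10]
  got <- machine_accepts(m, shorts)
  want <- vapply(shorts, segments_ok, logical(1), USE.NAMES = FALSE)
  expect_equal(got, want)
  expect_true(any(want))  # the sample actually exercises accepting strings
})

test_that("machines serialize to JSON and back without changing behavior", {
  m <- build_rest_machine()
  js <- machine_to_json(m)
  m2 <- machine_from_json(js)
  inputs <- c("0.00", "-0.05", "0.5", "0.00.01", "", "-1")
  expect_equal(machine_accepts(m2, inputs), machine_accepts(m, inputs))
  path <- withr::local_tempfile(fileext = ".json")
  machine_to_json(build_qrs_machine(), path)
  m3 <- machine_from_json(path)
  expect_true(run_automaton(m3, "0.9-0.4")$accepted)
})
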