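Package: qrslex
Title: Grammar-Based QRS Complex Detection in Single-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects QRS complexes in single-lead electrocardiograms by
    lexical analysis of the normalized amplitude stream. Samples are
    serialized to fixed-point decimal strings, classified into positive,
    negative and rest symbols by regular expressions realized as
    epsilon-NFA machines, grouped into maximal same-class tokens, and
    assembled into QRS complexes under standard-deviation and duration
    constraints. Includes RR-interval and QRS-duration rhythm statistics
    with regularity flags, beat-level sensitivity/positive-predictivity
    scoring against reference annotations, SNR-controlled noise injection
    for robustness sweeps, a synthetic ECG generator with exact ground
    truth, CSV and WFDB readers, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
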