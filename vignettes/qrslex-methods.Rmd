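---
title: "Grammar-based QRS detection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grammar-based QRS detection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrslex)
```

## The model

`qrslex` treats a normalized single-lead ECG as a string language. After
preprocessing, every sample lies in [-1, 1] and is serialized to a
fixed-point decimal string over the alphabet Σ = {0..9, `-`, `.`}. Three
regular sub-languages classify samples: positive-peak samples
`(0.[1-9][0-9]*|1)+` (value ≥ 0.1), negative-peak samples
`(-0.[1-9][0-9]*|-1)+` (value ≤ -0.1), and rest samples `(-?0.0[0-9]*)+`
(magnitude < 0.1). Maximal same-class runs are the lexemes ("tokens") of
the signal; a QRS complex is a token sentence

    QRS = {Q}? {rest}? {R} {rest}? {S}

with Q and the rests optional, recognized by finite-state machines. Pure
pattern matching over-generates, so each token must also satisfy two
statistical constraints computed from its k samples a_1..a_k at sampling
rate Fe: the population standard deviation sigma = sqrt(sum((a_i - mean)^2) / k)
and the duration Delta = k / Fe. QRS deflections are narrow and steep
(high sigma, Delta below 0.1 s); P and T waves are broad and flat (low
sigma, Delta above 0.1 s). The constraints are:

| token | role | sigma constraint | duration constraint |
|-------|------|------------------|---------------------|
| POS | R candidate | sigma > sigma1 | Delta < Delta1 |
| NEG | Q candidate | sigma > sigma1 / 2 | Delta < Delta1 |
| NEG | S candidate | sigma > sigma1 | Delta < Delta1 |
| REST | rest phase | — | Delta < Delta1 / 2 |

with sigma1 = 0.1 (dimensionless) and Delta1 = 0.1 s. The asymmetry
between Q (sigma1/2) and S (sigma1) is part of the method's definition and
is implemented as stated; Q deflections are genuinely shallower in most
leads, which is the empirical motivation.

### Assumptions

* Single lead, R peak pointing up. A predominantly negative QRS (deep QS
  morphology) will normalize with the S as the extremum and the method
  will under-detect; `detector_config(strict_s = FALSE)` relaxes the
  mandatory-S rule for morphologies without a distinct S but is off by
  default because the grammar prints S as mandatory.
* The R deflection dominates the normalized amplitude range. Normalization
  is global over the record, so a single huge artifact compresses all true
  beats toward the rest band. No attempt to window the normalization is
  made; this is a faithful-implementation choice, and long noisy records
  are the known cost (see Limitations).

## The processing chain

1. **Band-pass filter** 5–15 Hz, the band that concentrates QRS energy
   while rejecting baseline wander (< 1 Hz), powerline hum and most T-wave
   energy. The realization is a 2nd-order Butterworth applied forward and
   backward (`signal::filtfilt`), i.e. zero phase, so fiducial timing is
   not shifted — the tests hold peak displacement on a symmetric pulse to
   at most one sample. Boundaries are handled by reflect-and-invert
   padding (one second or the warm-up length, whichever is larger) so
   filter transients do not fabricate edge tokens.
2. **Centre** to zero mean.
3. **Normalize** by the maximum *absolute* deviation. Dividing by the
   maximum positive deviation alone would not bound deep negative
   deflections at -1, so the scale is max(|x - mean|); the extremum then
   attains magnitude exactly 1. A constant signal has zero scale and is a
   hard error, never a silent division.
4. **Serialize and tokenize** (precision below), **label** tokens with the
   constraint table, **assemble** complexes, **locate** R fiducials.

## Tunable parameters

| parameter | default | units | why |
|-----------|---------|-------|-----|
| `filter.low_hz` / `high_hz` | 5 / 15 | Hz | QRS energy band |
| `filter.order` | 2 | — | gentle rolloff; doubled by the two passes |
| `sigma1` | 0.1 | normalized amplitude | separates peak sigma (> 0.2 for R/S, > 0.1 for Q) from wave sigma (< 0.05) |
| `delta1` | 0.1 | s | peak durations < 0.1 s, P/T durations > 0.1 s |
| `precision` | 3 | decimal digits | see Numerical choices |
| `strict_s` | `TRUE` | — | grammar prints S mandatory |
| `tolerance_s` (scoring) | 0.15 | s | conventional beat-matching window; the package's own tests use the stricter 0.05 s |

## Numerical choices

* **Serialization precision**: 3 fractional digits, round-half-even
  (R's `round`). The method's source formulation never states the
  precision it used; 3 digits resolves the 0.1 class boundary with two
  spare digits and keeps token strings short. Classification uses the
  *rounded* value, so the numeric view (thresholds at ±0.1) and the string
  view (regex match) provably coincide — an amplitude of 0.0999 rounds to
  0.100, which is POS under both. The equivalence is asserted over the
  whole grid -1.000, -0.999, …, 1.000.
* **Population standard deviation** (divisor k) everywhere: token sigma,
  σRR, σQRS. The σRR formula is implemented with the squared deviation;
  one printed form of it drops the square, which is treated as a typo
  since the companion σQRS formula and the token-sigma formula both square.
* **Strict thresholds**: all constraint inequalities are strict as printed
  (σ > σ1, Δ < Δ1); the regularity flag is regular iff sigma < 0.1, so a
  sigma of exactly 0.1 is irregular.
* **Tie-break**: the R fiducial is the argmax of the R token, earliest
  index on plateaus.
* **Degenerate inputs**: constant/zero signals error at normalization;
  empty tokens error; fewer than two fiducials give an empty RR series
  with a warning and an all-NA summary rather than fake zeros; zero
  denominators in Se/Sp yield NA, never 0.

## The automata engine

The published transition tables for the four machines label themselves
deterministic but contain epsilon-moves and duplicate entries, so the
engine executes them as epsilon-NFAs (closure + subset simulation), which
is well-defined and deterministic in outcome. The contract is that each
machine's language equals its defining regular expression, and the test
suite enforces it against R's own regex engine on the full serialized
amplitude grid and on 10^4 random Σ-strings.

Two moves missing from the printed composite-QRS table were added to honor
that contract: the path from the start state into the leading rest block
(the expression allows a rest with Q absent) and the fractional-digit loop
in the R section (without it `0.55` would be rejected). Digit-range
shorthands (`0-9`, `1-9`) expand to per-digit transitions at build time.
Patterns are anchored to whole strings; the `consumed` count from
`run_automaton()` is diagnostic only.

## Assembly

Greedy left-to-right, no backtracking across emitted beats: each unconsumed
R candidate grabs an adjacent optional rest/Q on the left and an optional
rest plus the mandatory S on the right; every token is consumed at most
once. Two consequences worth knowing:

* A NEG token wedged between two R candidates is taken as the S of the
  left beat, never the Q of the right one — the grammar consumes S before
  a new sentence starts.
* In strict mode an R candidate with no qualifying S within one rest is
  consumed without emitting a beat. There is no refractory period; double
  detection is prevented structurally by token consumption.

The complex's onset/offset span every consumed token, so the reported QRS
duration includes the intra-complex rest gaps.

## Evaluation

Beat matching is greedy one-to-one in time order within ±`tolerance_s`;
the matching window is a free parameter of any beat-level score and must
be stated for Se/Sp to be well-defined. "Specificity" follows this
method's usage, TP/(TP+FP) — positive predictivity, not the
epidemiological specificity; the naming is kept for comparability and
documented everywhere it appears. Display rounding is half-up to two
decimals, with raw values retained.

Noise robustness uses additive white Gaussian noise scaled to a target
SNR, with power measured as mean squared deviation about the mean (a DC
offset is not signal power); the realization is fixed by a seed. The noise
kind is the simplest defensible choice — real ECG noise (muscle artifact,
electrode motion) is colored and nonstationary, so the sweep
characterizes robustness to broadband corruption only.

## The synthetic generator

`synth_ecg()` builds each beat as five Gaussian bumps (P, Q, R, S, T) at
configurable amplitude, full width, and offset from the R centre, on an
optional sinusoidal baseline drift, with RR intervals drawn from a normal
distribution floored at 0.3 s so beats never collide. Defaults: amplitudes
P 0.10, Q -0.15, R 1.00, S -0.45, T 0.25 (fractions of R); full widths
Q 0.04, R 0.05, S 0.04 s (below Delta1) and P 0.11, T 0.22 s (above
Delta1); the Gaussian sd is a quarter of the full width. These place the
token statistics exactly where the detector's premises put real peaks and
waves — verified empirically by running the lexer on generated output, not
assumed. Ground truth is exact by construction (`diff(r_index)/fs` *is*
the RR series), so closure tests can demand Se = 100 % and FP = 0 rather
than "high".

What the generator does **not** emulate: beat-to-beat morphology change,
ectopy, conduction abnormalities (wide QRS, QS complexes), colored noise,
electrode motion, or amplitude modulation with respiration. Passing the
closure suite therefore shows the chain is correct *under the method's own
morphological premises*; it does not predict benchmark-database
performance, which additionally depends on morphologies that violate the
strict-S grammar and on the (unstated) matching tolerance of the original
evaluation. Replicating the published database-wide rates is explicitly
out of scope here; a local MIT-BIH-style copy can be run through
`read_wfdb_record()` + `detect_qrs()` by anyone holding the data.

## Problem sizes in the shipped tests

The closure suite runs ten 5-minute, 360 Hz fixtures (60–100 bpm, regular
and 0.05 s-jitter), the regularity regimes two more 5-minute fixtures
(jitter 0 and 0.15 s at mean RR 0.84 s), and the SNR sweep a 60-second
fixture at 90/40/30/20 dB with five seeds per level — sizes chosen so the
statistics are stable (hundreds of beats per fixture) while the whole
suite stays interactive.

## Known limitations

* Strict-S under-detects QS and RS-less morphologies (documented lenient
  mode exists).
* Global normalization is brittle to single large artifacts.
* At very low SNR the band-pass is the only defence; there is no adaptive
  thresholding, so sensitivity collapses more sharply than in detectors
  with decision logic.
* Offline only: the implementation processes complete records; no
  streaming state machine is provided.
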