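---
title: "Methods: lateralization metrics, normative ranges and staircase simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lateralization metrics, normative ranges and staircase simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binlat)
```

This vignette documents the models, conventions and numerical choices
behind the package, in the order the pipeline applies them.

## 1. The lateralization task and the 31-metric profile

A session presents, interleaved and in random order, ITDs of ±200, ±400,
±600 µs (physiological) and ±1500 µs (beyond the physiological range),
ILDs of ±4, ±8, ±12 dB, monaural left/right stimulation, and the diotic
stimulus — identical signals at both ears, the shared zero of both cue
continua.  Responses are the keys 1–9 (5 = intracranial midline; one key
= 1/8 of the inter-ear distance).  Every stimulus is presented six times,
the diotic one eight times, and the first response per stimulus is
discarded as practice (`retain_trials()`), leaving 5 retained trials per
stimulus and 7 diotic trials.

The 31 metrics (`metric_names()`) summarize four aspects of the retained
responses:

* **Slopes (6, cluster C).**  Ordinary least squares of response key on
  cue value over the three left-favoring and, separately, the three
  right-favoring physiological stimuli of each family.  The fit runs
  over *individual retained trials*, not per-stimulus means: with
  balanced counts the two are algebraically identical (this identity is
  property-tested), and trial-level fitting stays well-defined for
  incomplete sessions.  The side asymmetry is `log(L slope / R slope)`;
  every "logarithmic ratio" metric in the package uses the natural log —
  the base is a pure rescaling and all downstream classification is
  rescale-invariant.  A non-positive slope quotient leaves the ratio
  undefined (`NA`).
* **Shift (9, cluster A).**  Family mean responses, side-fit means (the
  fitted value at the middle stimulus of each side triplet), perceived
  centers (mean *cue value*, in native µs/dB, of trials answered with
  key 5 — `NA` when key 5 never occurs), and the diotic percept.
* **Variability (9, cluster B).**  Per-stimulus sample standard
  deviations (n−1 denominator — with only 5–7 trials per stimulus the
  unbiased convention matters and is stated explicitly), averaged over
  the family's physiological set and over each side triplet, with
  left/right log ratios.
* **Ranges (3, cluster D), monaural (2, E), extremes (2, F).**  Range =
  max − min of per-stimulus mean responses within a family; range ratio
  = `log(ILD range / ITD range)`; the monaural and ±1500 µs stimuli are
  summarized only as mean responses and enter no other metric.

**Membership conventions.**  The diotic stimulus carries zero ITD *and*
zero ILD, so its retained trials participate in both families' means,
standard deviations, ranges and centers (at cue 0).  The ±1500 µs and
monaural stimuli are excluded from everything but their four dedicated
means.

**Floors before log ratios.**  Side standard deviations are floored at
0.1 keys and ranges at 0.5 keys before forming log ratios.  Without the
floors, a deterministic listener (all per-stimulus responses identical —
exactly what side-oriented patients produce) would have `log(0/0)`
ratios; with them, the symmetric degenerate case lands at 0 and stays
comparable across sessions.  The floor values are conventions of this
package: 0.1 keys is far below any observable sample SD of integer
responses that differ at all (the smallest nonzero SD of five keys is
0.447), and 0.5 keys is half a response button.

**Quantization.**  Responses are integer keys, which slightly flattens
idealized expectations: a perfectly linear noiseless listener whose
percepts fall at thirds of keys produces retained responses 1, 2, 4 /
6, 8, 9 and hence OLS slopes of 0.375 keys/dB (ILD) and 0.0075 keys/µs
(ITD) rather than the continuous-response 4/12 and 4/600.  The test
suite freezes the quantized values, which every entry of the
noiseless-listener metric vector forces exactly.

## 2. Normative ranges and divergence counting

Per metric, the control cohort's values are sorted ascending and the
normal range spans the **2nd to the (n−1)th value, inclusive**
(`normal_range()`); for the canonical 12-member control group, the 2nd to
the 11th.  Classification uses values, not positions, so a patient tied
with the control minimum is normal whenever that minimum equals the 2nd
value.  By construction exactly 2/n of distinct control values fall
outside their own range, i.e. 31 × 2/12 ≈ 5.17 expected false
divergences per participant — hence the rule that **≤ 5 divergences ⇒
normal lateralization** (`divergence_profile()`).

Two `NA` policies are deliberate package decisions:

* `NA` *control* values (e.g. an undefined slope ratio) are dropped and
  the positional rule is applied to the remaining n valid values —
  mirroring how invalid control staircase tracks are handled for the
  BMLD normal range.
* `NA` *patient* values count as divergent (flagged distinctly as
  `na_divergent`).  A metric that is undefinable for a patient while
  defined for every control is itself a deviation; skipping it would
  reward degenerate response patterns such as never pressing key 5.

## 3. Longitudinal change

Between two phases, each metric's change is
`(|x_earlier − µ| − |x_later − µ|) / s` with µ the control mean and `s`
the control dispersion: positive = the later measurement moved toward
the control mean.  The score is antisymmetric under phase swap and
bounded by `(|x_e − µ| + |x_l − µ|)/s`.

The dispersion unit is the **control standard deviation** by default.
The source conventions are ambiguous on this point (SD in the methods
and figure caption, IQR in one results paragraph); the package follows
the majority reading and exposes `dispersion = "iqr"` as a switch.  If
either phase's value is `NA` the change is `NA` and excluded from
cluster summaries.

Trajectories come from divergence counts alone: improved / stable /
deteriorated as the later count is smaller / equal / larger.  Reported
phase pairs are the adjacent ones plus first-vs-last (acute–subacute,
acute–chronic, subacute–chronic), matching the three standard panels.
The metric→cluster map A–F (`metric_clusters()`) assigns the nine shift
metrics to A, nine variability metrics to B, six slope metrics to C,
three ranges to D, monaural to E and extremes to F; the assignment
follows the cluster titles, which name groups rather than enumerate
members.

## 4. Staircase simulation and BMLD

The observer is a 3AFC cumulative normal:
`p(L) = 1/3 + (2/3 − lapse)·Φ((L − µ)/σ)`, lapse 0 by default.  The
one-up/three-down rule lowers the level after three consecutive correct
responses (the counter resets after every level change — the standard
transformed up-down convention, stated here because sources rarely spell
it out) and raises it after any error.  It converges to
`p = (1/2)^(1/3) ≈ 0.794`.

Numerical conventions:

* **Ten reversals total**: steps of 4 dB up to the second reversal, 2 dB
  for the remaining eight; the change triggered *on* the second-reversal
  trial still uses 4 dB.  Threshold = mean of reversal levels 3–10.  The
  reversal level is the level presented on the trial at which the
  direction change occurred.
* **Cap policy**: requested levels above 80 dB SPL are clamped; three
  above-cap requests invalidate the track (threshold `NA`).  In the
  human protocol an experimenter re-instructs and then aborts; a counter
  is the mechanical analogue and is configurable.
* Condition start levels: 65 dB SPL (N0S0), 50 dB SPL (N0Sπ).  BMLD =
  N0S0 threshold − better (lower) of the two N0Sπ runs; the cohort
  simulator runs the two N0Sπ tracks first, as in the measurement
  protocol, though runs are statistically independent here (no
  order-effects model).

The analytic check used in tests: the mean extracted threshold over many
tracks must lie within 1 dB of `µ + σ·Φ⁻¹((0.794 − 1/3)/(2/3))`
≈ `µ + 0.498 σ`, for σ between 1 and 8 dB.

## 5. The synthetic cohort: what it emulates, and what not

`simulate_session()` maps cue to latent percept
`p = 5 + 4·gain·sat(cue) + bias`, `sat(cue) = clamp(cue/span, −1, 1)`
(span 600 µs / 12 dB; ±1500 µs saturates), overridden to
`5 + sign(cue)·4·gain + bias` for side-oriented listeners and to fixed
targets for monaural stimuli.  With probability `confusion_prob` a
lateralized percept is mirrored about key 5; an extra
`extreme_confusion_prob` mirrors only the ±1500 µs percepts
(reproducing extreme-ITD reversals seen clinically).  The button press
is `clamp(round(p + N(0, noise²)), 1, 9)` — noise added to the
continuous percept, *then* rounding (half away from zero), *then*
clamping: the readout model of pressing the nearest button.  A
consequence worth knowing: exact half-key percepts are unattainable as
session means, so exact parameter-recovery statements hold only for
integer-valued biases, and a large bias pushes one side into the key-9
clamp and flattens that side's slope.

Controls are drawn with gain jitter ±10 %, bias ±0.3 keys and response
noise SD 0.4–0.8 keys — conventions chosen once to make control metric
spreads resemble a plausible healthy cohort (no quantitative control
noise distribution is published).  Patient archetypes (`shifted`,
`side_oriented`, `high_variability`, `confuser`) blend a control-like
base draw toward archetype parameters (bias 2 keys, noise SD 1.5 keys,
confusion 0.3, side-orientation) by a per-phase severity, with
trajectories `recovering` (1 → 0.5 → 0.15), `deteriorating`
(0.3 → 0.65 → 1) and `stable` (0.8).  Tone-in-noise observers share one
distribution across groups (BMLD ≈ 10–16 dB), reflecting that binaural
unmasking is largely spared by stroke in this population.

**Seeding.**  Every participant × phase consumes an RNG substream whose
seed is derived from the master seed by a polynomial string hash of
`"id/phase"` modulo 2³¹−1, so enlarging a cohort never perturbs existing
participants and identical seeds give byte-identical files.

**What a green test does not establish.**  The generator emulates
response *statistics* (shifts, side-orientation, confusions, noise), not
audio, attention lapses, learning across phases, lesion anatomy, or the
correlation structure of real patients; cohort-level clinical results
(normal-lateralization percentages, BMLD normal range 7.5–18.5 dB,
improvement-vs-deterioration case counts) depend on the real cohort and
are out of reach at desk scale — the tests instead verify the machinery
by properties: oracle equality, mirror symmetry, parameter recovery,
antisymmetry of change scores, and the 5/6 classification flip.

## 6. File-format and interface decisions

UTF-8, comma-delimited, `.` decimal separator, one header row; the
undefined-value sentinel is the literal token `NA`.  Metrics are
serialized at full double precision (`%.17g`) so write/read round-trips
are exact; for that reason ITD slopes stay in keys/µs on disk rather
than a ×100 "keys per 100 µs" display scaling, which a binary-decimal
round trip cannot survive losslessly.  Normative tables are JSON (one
object per metric: `lo`, `hi`, `mean`, `sd`, `iqr`, `n_controls`).  The
CLI's optional `--config` file is JSON as well, keeping the package's
single structured-data dependency (`jsonlite`).  Phases are free
strings ordered by configuration, with acute/subacute/chronic as the
default, so two-phase subsets work throughout.

## 7. Known limitations

* No psychometric (sigmoid) modeling of lateralization percepts and no
  goodness-of-fit statistics; the metric set is deliberately the fixed
  31-variable profile.
* Group-level hypothesis tests (Kruskal–Wallis, Dunn, Spearman, ANOVA)
  are out of scope; stock routines apply directly to the tables this
  package writes.
* The staircase simulator abstracts signal detection into (µ, σ) per
  condition; it does not model stimulus acoustics or calibration.
* Order-statistic ranges from 12 controls are coarse (16.67 % in-sample
  false-divergence rate per metric is inherent to the rule, not a bug).
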