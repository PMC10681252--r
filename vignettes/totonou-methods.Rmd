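---
title: "Methods: ERP, band-power and brain-state decoding for sauna EEG studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ERP, band-power and brain-state decoding for sauna EEG studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(totonou)
```

This vignette is the package's own account of the analysis it implements:
the models and procedures, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where the underlying description left the design open.

## Study layout and data model

The package analyses a two-group design (sauna vs. control, equal sizes)
with four measurement occasions: a pre-sauna baseline and the rest step of
each of three alternating hot/cold sets (`post1`, `post2`, `post3`). Two
recording streams feed different paths:

* **Scalp oddball sessions** (`pre`, `post3`): channels Fz, Cz, Pz plus one
  EOG channel at 500 Hz, recorded during a 200-stimulus auditory oddball
  task (80% standards, 20% targets, 1.5 s onset asynchrony, at least two
  standards between targets).
* **In-ear rest recordings** (all four stages): channels L and R at 600 Hz,
  eyes closed.

Everything is carried in a single container, `eeg_recording` (channels ×
time in microvolts, with a sampling rate and channel labels); events are a
separate table keyed by 0-based sample index. All windows in the package are
half-open `[start, end)`, and every stage checks the channel labels it
needs (`require_channels`), so scalp data cannot silently flow into the
in-ear path.

## Scalp path: ERP quantification

1. **Filtering.** Zero-phase band-pass, 0.1–30 Hz. The response is the
   squared magnitude of a 4th-order Butterworth — what forward-backward
   filtering realizes — applied in the frequency domain with mirror padding.
   A time-domain recursion with transfer-function coefficients is
   numerically ill-conditioned at a normalized cutoff of 0.1 Hz / 250 Hz
   (the filtered output of a DC-offset signal retains multi-microvolt
   residue); the frequency-domain realization is exact at any cutoff and
   keeps component latencies unshifted. Passband amplitude is preserved
   within 5% and a stopband tone at twice the upper cutoff is attenuated by
   more than 99% (both asserted by tests).
2. **Epoching.** −100 to +600 ms around each stimulus, baseline-corrected by
   the mean of `[−100, 0)` ms per channel. Markers whose window crosses a
   recording edge are dropped with reason `"edge"` and counted.
3. **Artifact rejection.** An epoch is rejected when any monitored channel
   (EOG included) exceeds ±50 µV. The threshold is applied to the filtered,
   baseline-corrected amplitudes: the rejection step sits after filtering
   and epoching in the pipeline, so the quantity it sees is the quantity
   later averaged. Rejection only flags epochs — sample data are never
   mutated, and kept + rejected always equals the total.
4. **Averaging and scoring.** Kept epochs are averaged per condition; the
   difference waveform is target minus standard, per channel (never pooled
   across electrodes). MMN is scored over `[100, 250)` ms, P300 over
   `[240, 400)` ms.

**Area vs. peak.** "The area of the negative peak" is self-contradictory as
a measure definition. The primary measure here is the polarity-clipped
trapezoidal area (µV·ms): integrate `min(d, 0)` for MMN, `max(d, 0)` for
P300, over the scoring window. This is robust to noise riding on the
component and matches the "area" wording; the extremum amplitude and its
latency are always reported alongside, and `measure = "peak"` switches the
headline columns to them. Areas are signed (MMN ≤ 0 by convention);
"MMN increased" means its magnitude grew.

Reaction times are summarised over correct target responses only
(mean, SD, n).

## In-ear path: IAF-anchored band power

In-ear recordings are filtered 2–30 Hz, cut into non-overlapping 8-s
segments (trailing remainder discarded), and segments exceeding ±100 µV are
rejected. Each kept segment yields a one-sided periodogram with a **Hann
taper**, renormalized by the taper's mean square so that broadband power and
sinusoid power are both preserved: the spectrum of an 8-s unit sinusoid sums
to 1/2 and the untapered variant satisfies Parseval exactly (both asserted).
The Hann taper is not part of the stated procedure; it was chosen because
rectangular-window leakage from the alpha peak would contaminate the narrow
(2 Hz) adjacent bands.

The **individual alpha frequency** is the argmax of the segment- and
channel-averaged power within 8–13 Hz (inclusive) of the *pre-stage*
spectra, ties broken toward the lower frequency, reported on the 0.125 Hz
grid. Using both channels' average is a choice: the source description does
not say which channel defines the peak.

Band powers are sums of bin powers over half-open, lower-inclusive
intervals — theta `[IAF−6, IAF−4)`, lower-1 `[IAF−4, IAF−2)`, lower-2
`[IAF−2, IAF)`, upper `[IAF, IAF+2)`, beta `[15, 30)` — averaged across kept
segments, separately for L and R. Half-open edges make the four
IAF-anchored bands an exact partition of `[IAF−6, IAF+2)` (a test asserts
adjacency and that the four powers sum to the total over that range);
"gross absolute power" is implemented as the *sum* (not mean) of bin powers,
which is monotone-equivalent and stated here for reproducibility.

## Group statistics

`mixed_anova` fits the balanced two-way mixed design via `stats::aov` with
an `Error(participant)` stratum: the group effect is tested against the
between-subject error, the set effect and the group × set interaction
against the subject × set error. The design must be complete and balanced;
missing cells raise a typed error (no imputation), and fewer than two
participants per group is "insufficient replication". Three-way designs with
electrode as a factor are deliberately reduced to per-electrode two-way
ANOVAs. Sums of squares at numerical-noise scale (relative 1e-10) are
treated as zero so constant data report F = 0 rather than a noise/noise
ratio. No sphericity correction is applied by default.

**Simple main effects** test the set effect separately inside each group
against the *pooled* within-subject error of the full model. With two groups
of 10 and four sets this yields F(3, 54) — the df structure of the reported
omnibus tests — and is the conventional decomposition; whether the original
analysis pooled or refit per group is not stated, so the pooled form is the
one implemented and documented here.

**Holm–Bonferroni pairwise comparisons** of set means use
`t = Δm / sqrt(2·MSe/n)` with the pooled within error and its df, adjusted
by Holm's step-down rule (`stats::p.adjust`); flags are reported at 0.05 and
(marginally) 0.1. `set_effect_pattern` combines these: a band's contrasts
are only inspected when the sauna group's simple main effect is significant,
which mirrors how such post-hoc tables are gated.

Pearson change correlations (post3 − pre deltas of band power vs.
questionnaire items) and the one-sample t against 50% chance are thin
wrappers over `stats::cor.test` / `stats::t.test` with typed errors for
degenerate input (n < 3, zero variance).

## The decoder

Classes follow the session stage: `pre` → non-totonou; `post1`–`post3` →
totonou. The pipeline order is fixed and recorded in the output:

```
segment → FFT power → noise screen → balance → split →
standardize(train) → PCA(train) → λ-CV → fit → test
```

* **Features.** 4-s segments; per-segment power at 0.5 Hz steps over
  4–40 Hz (73 steps, by summing the two constituent 0.25 Hz FFT bins) for
  three signals — L, R, and the time-domain difference L − R — giving 219
  columns.
* **Decoder filter band.** Features are computed from data filtered
  2–45 Hz, *not* the in-ear analysis band of 2–30 Hz: a 30 Hz low-pass
  would null the 30–40 Hz third of the feature grid that the feature
  definition requires. The two stated passages conflict; the 2–45 Hz choice
  keeps every feature informative.
* **Noise screen.** The original screening criteria were derived from a
  separate clean-data corpus that is not available; the operative rule here
  is within-recording: a segment is excluded when its broadband power
  (row sum over the feature grid) exceeds the participant's mean + 2 SD.
  Zero-spread participants keep all segments. On Gaussian scores this
  excludes the upper ~2.3% tail (asserted by a Monte-Carlo test).
* **Balancing.** Within participant, the majority class (totonou pools
  three sets against one) is subsampled without replacement to the minority
  count, deterministically per seed.
* **Leakage guard.** Whether standardization and PCA were fit before or
  after the train/test split is not stated. Default: within-participant
  per-column standardization and the PCA basis are fit on training rows
  only and applied unchanged to test rows. A mutation test asserts the
  guard: perturbing test rows leaves the fitted model bit-identical.
  `standardize = "global"` restores the fit-on-everything variant for
  comparison.
* **Sparse discriminant.** "LDA with LASSO" is realized as an L1-penalised
  logistic discriminant on the PCA scores (`glmnet`), a standard surrogate
  with the same sparse linear decision rule. λ is selected over a 50-value
  log-spaced grid by 10-fold stratified CV minimizing misclassification,
  ties resolved toward the larger (sparser) λ; weights are refit on all
  training rows at the chosen λ.
* **Evaluation.** Stratified 90/10 splits within participant. A single
  split is high-variance (with 40 balanced segments the test set holds 4),
  so the default reports the mean over 20 seeded splits (`n_splits = 1`
  gives the single-split variant). Group accuracy is tested against 50%
  with the one-sample t.

## The synthetic generator

The generator exists so that every stage above is exercised end-to-end with
known ground truth. What it emulates:

* **Oddball sessions.** Stimulus sequences with the exact count/fraction/gap
  constraints; MMN and P300 as Gaussian deflections (default −5 µV at
  175 ms and +6 µV at 320 ms, SD 20 ms — centred in their scoring windows,
  with ≥90% of each component's mass inside its window enforced at
  construction); background as an equal-power mix of pink (1/f) and white
  noise (default SD 8 µV); blinks as 300 ms half-sines on EOG (default
  120 µV, 2/min) bleeding 20% into scalp channels; log-normal reaction
  times (median 400 ms) recorded on correct targets.
* **In-ear rest.** Frequency-domain synthesis with random phases: a pink
  baseline plus the five analysis bands, each rescaled so its realized band
  power equals its target exactly; the two alpha bands adjacent to the IAF
  take Gaussian-flank shapes peaking at the IAF, plus a concentrated
  oscillation at the IAF itself (counted toward the upper-alpha target) so
  the spectrum shows the sharp individual alpha peak real resting EEG has.
  Oscillations are therefore narrow-band noise, not pure sinusoids. Muscle
  bursts (100 ms, default 150 µV) are inserted at a configurable rate;
  artifact and blink onset times are attached as attributes so rejection
  bookkeeping can be checked against the schedule.
* **Cohorts.** Per participant: an IAF drawn uniformly from 9–11.5 Hz,
  log-normal between-participant band-power multipliers (SD 0.2 on the log
  scale), log-normal stage-to-stage noise (0.1), the design's multiplicative
  stage factors for the sauna group (identity for controls), ERP amplitude
  deltas at post3 for the sauna group (MMN deepens by 3 µV, P300 shrinks by
  2.5 µV), a −40 ms median RT shift, and 29 questionnaire items on a 0–100
  scale of which Q2, Q4 and Q14 are coupled to the participant's injected
  theta-power change at correlation 0.77. The default stage factors rise in
  the reported direction: theta ×(1, 1.9, 2.1, 2.2) and lower-1 alpha
  ×(1, 1.8, 2.0, 2.1) from the first set, lower-2 and upper alpha
  ×(1, 1.05, 1.9, 2.0) from the second, beta flat. Magnitudes are package
  defaults chosen once to be generous — the underlying study publishes no
  raw-data distributional parameters, so no synthetic magnitude is a
  published value.

Everything is a deterministic function of the design seed: identical seeds
give bit-identical cohorts and files.

What it does **not** emulate: volume conduction or any biophysical head
model; non-stationarity within a rest recording; heart rate, electrodermal
or salivary measures; realistic questionnaire response styles; device
quantization or line noise. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline recovers what was injected under the stated
noise model — not that the pipeline's assumptions hold for any particular
real recording.

## Problem sizes and tolerances used in the tests

Test cohorts use 10 participants per group with 32-s rest recordings (four
8-s segments per stage) for the band-power statistics, and 80-s recordings
(80 four-second segments per participant) for decoder evaluations — large
enough for stable spectra while keeping the suite quick. Key tolerances:
noiseless component areas within 5% of the closed-form Gaussian integral
`A·σ·√(2π)`; filtering perturbs noiseless areas by <5%; IAF recovery within
one 0.125 Hz bin; realized band-power ratios within 20% over 10 seeds;
label-shuffled decoding within 3 standard errors of 50%; the mixed ANOVA
equals a brute-force sums-of-squares oracle to 1e-8 and its interaction
type-I error sits within two binomial standard errors of 0.05 over 2000
null replicates.

## Interfaces and scope

The exported functions are the interface; `scripts/acceptance.R` is a thin
command-line driver over them, and recordings/tables round-trip through
plain delimited text (with a YAML metadata sidecar) or minimal 16-bit EDF.
No shell subcommand dispatcher is shipped: for an analysis package of this
kind the R API plus the vignette serve that role. Proprietary device
formats, online/streaming acquisition, ICA-based ocular correction,
sphericity corrections, source localization, cross-participant transfer
decoding and neurofeedback are out of scope.

## Known limitations

* The mixed ANOVA requires complete balanced designs; dropouts must be
  handled upstream.
* Band-power values depend on the analysis filter (the 30 Hz low-pass
  attenuates the top of the beta band); comparisons across stages are
  unaffected, absolute values are pipeline-specific.
* The Holm pairwise test uses the pooled within error; with strongly
  heteroscedastic stage variances (multiplicative effects) it is
  approximate.
* Decoder accuracies from 4-row test sets are coarse; the 20-split mean is
  the stable quantity, and single-split results should be interpreted with
  that granularity in mind.
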