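---
title: "Classifying dairy-cow posture and behavior from flank accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying dairy-cow posture and behavior from flank accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cowaccel)
```

## The measurement problem

A triaxial accelerometer fixed over a cow's left paralumbar fossa measures,
at every instant, the sum of a *static* component — the gravity vector
expressed in the sensor's frame, which rotates when the animal changes
posture — and a *dynamic* component produced by body, jaw and leg movement.
Sampled at 5 Hz, the static part separates standing (S) from left and
right sternal recumbency (LSR, RSR), because lying rolls the flank so that
gravity loads the z axis (toward the ground in LSR, away from it in RSR)
instead of the x axis. The dynamic part carries the behavioral signature:
rumination is a regular ~1 Hz jaw cycle, feeding a similar cycle with
stronger, burstier accelerations, walking a train of step impulses, while
resting and standing still are nearly quiescent.

The pipeline turns a labeled 5 Hz stream into a supervised classification
problem: cut the stream into 8 s windows, summarize each window with 36
statistics, prune redundant statistics, and train a classifier per task
(3-class posture, 5-class behavior).

## Units and conventions

Acceleration is treated throughout in gravitational units (g), so a
motionless sensor reads magnitude `amag = sqrt(x² + y² + z²) ≈ 1`. The
logger export format is not standardized, so `read_sensor_csv()` takes a
configurable `csv_dialect()` (column names, separator, decimal mark); the
documented default — `date`, `time` with hundredths, `X`, `Y`, `Z`,
comma-separated — is what the package fixtures use.

Observer annotations are half-open intervals `[start, end)`: a sample
sitting exactly on a boundary belongs to the later interval, so abutting
intervals can never double-label a sample. Samples covered by no interval
are treated exactly like samples the observers flagged as non-univocal:
both carry the `AMBIGUOUS` sentinel and are removed by `drop_ambiguous()`
before windowing, with a removal report (counts and minutes, at 5 Hz one
sample = 1/300 min) mirroring the per-animal bookkeeping of the motivating
study.

## Windowing

`segment_windows()` places candidate windows of 40 samples (8 s) every 13
samples, i.e. `floor((n − 40)/13) + 1` candidates for an `n`-sample
stream. A candidate is retained only if all 40 samples carry one identical,
non-ambiguous label for the task at hand; posture and behavior streams are
therefore windowed independently and generally yield different retained
counts. Both parameters are exposed (`window`, `stride`) so the 8 s design
can be re-examined.

One bookkeeping subtlety: summaries of this design sometimes quote the
candidate count as `floor(n/13)`, which for very long streams exceeds the
true strided count by up to 3 windows (the last partial window never
fits). `candidate_count()` implements the exact arithmetic; the shorthand
is reported alongside it in the acceptance script because published row
counts use it.

## The 36 features

For each window and each channel (x, y, z, amag), `window_stats()`
computes:

| stat | definition | convention |
|------|------------|------------|
| avg  | arithmetic mean | — |
| sd   | sample SD | n − 1 denominator |
| zc   | zero crossings | after mean-centering; exact zeros keep the previous non-zero sign |
| p2p  | max − min | — |
| rms  | √(mean of squares) | — |
| kur  | m₄/m₂² − 3 | excess, moment estimator (n denominator) |
| skw  | m₃/m₂^1.5 | moment estimator |
| cf   | max(abs(w)) / rms | crest factor |
| Vrms | rms of cumulative sum | zero initial condition, no Δt factor (g·sample) |

Mean-centering before counting zero crossings matters: without removing the
~1 g gravity offset the x, z and amag channels would almost never change
sign and the feature would be uninformative. Any affine rescaling beyond
centering would leave the count unchanged, so centering is sufficient. The
`Vrms` integral deliberately uses the raw signal (the discrete inverse of
first differences) rather than the centered one; on windows with a nonzero
mean it is dominated by the accumulated offset, which itself discriminates
postures.

Degenerate windows (a channel with zero variance, possible only on
noise-free synthetic data) would make skewness, kurtosis and crest factor
0/0; they are returned as 0 with a counted note so the feature table stays
rectangular, rather than dropping rows inside the extraction step.

Two identities are enforced by tests on every extracted window:
`rms² = avg² + m₂` (with `m₂` the population variance), and invariance of
skw/kur/zc/cf under the appropriate affine maps.

## Feature pruning, split, normalization

`prune_correlated()` removes redundant features greedily: among all pairs
with absolute Pearson correlation ≥ 0.8 (the default cutoff), take the pair
with the largest |r| and discard the member with the larger mean absolute
correlation against all remaining features; repeat until no pair reaches
the cutoff. The procedure is the standard mean-absolute-correlation filter
and is deterministic given the table. Which 16–20 of the 36 features
survive depends on the data; on exhaustively enumerable toy problems the
greedy solution is verified to be a minimal valid removal set.

`split_normalize()` performs a plain uniform random split (default 75%
training) — not stratified and not grouped by animal, matching the
protocol being reimplemented — and z-scores all feature columns with the
training partition's mean and SD. A grouped (per-cow) split would be the
honest design for claims about generalization to unseen animals; it is
deliberately not the default because the reference protocol pooled windows
before splitting, but the split machinery accepts any pre-filtered table,
so a caller can split by cow upstream.

## Classifiers

Four standard backends are wrapped behind one interface
(`fit_predict()`): random forest (500 trees, √p candidates per split),
k-nearest neighbors (k = 5, Euclidean), extreme gradient boosting
(multiclass softmax, 200 rounds, depth 6, η = 0.3, single thread for
reproducibility) and an RBF support vector machine (C = 1, γ = 1/p). The
source protocol does not state hyperparameters, so these defaults are
ordinary textbook settings, fixed once and overridable per call; no tuning
or search is performed anywhere in the package.

## Assessment panel

`build_confusion()` lays out counts predicted-in-rows × actual-in-columns.
From a K×K matrix with total N and diagonal sum D:

- accuracy = D/N, with its **exact Clopper–Pearson 95% interval** (the
  default interval of R's `binom.test`);
- **no-information rate** NIR = (largest actual-class count)/N, and a
  one-sided exact binomial p-value for P(X ≥ D | N, NIR) — the null is
  "the classifier does no better than always predicting the most prevalent
  class";
- **Cohen's kappa** = (p₀ − p_e)/(1 − p_e) with
  p_e = Σ_k (rowsum_k × colsum_k)/N², undefined (NA) when p_e = 1;
- per class, via one-vs-rest counts (TP the diagonal entry, FP the rest of
  the row, FN the rest of the column, TN the remainder): sensitivity,
  specificity, precision, NPV, prevalence, and balanced accuracy
  = (Se + Sp)/2. Zero-denominator ratios are NA, never an error: a class
  can legitimately be absent from a test partition.

The per-class panel and the overall panel are verified in two independent
ways: against hand-enumerated toy matrices, and against
`caret::confusionMatrix` on random label vectors (the package never *uses*
caret; it is an oracle in the test suite only).

### Reproducing the published tables

The package ships, as plain-text fixtures, the eight test-set confusion
matrices (four models × posture/behavior) published for this sensor
configuration, together with the printed assessment tables.
`reproduce_tables()` recomputes every one of the 232 printed values from
the matrices and compares each at its own printed precision. A printed
value is accepted when it equals the rounding *or* the truncation of the
computed ratio at the printed number of decimals: 7 of the 232 published
entries (for example a posture accuracy printed 0.974 where the underlying
ratio is 7916/8123 = 0.97452) are truncations, and requiring strict
rounding would flag values that are in fact exactly reproduced. No
tolerance beyond one unit in the last printed decimal is used anywhere.
With the shipped fixtures the mismatch count is zero.

## The synthetic-data generator

No raw recordings are publicly deposited, so the package carries a
generator that emulates the statistical structure the analysis relies on —
not the physiology of a cow.

**Postures** set the static direction: S → (−1, 0, 0), LSR → (0, 0, −1),
RSR → (0, 0, +1), each tilted by a per-bout random rotation (SD 5°) and
renormalized, reflecting that a harness never sits at the same angle
twice. The three directions are mutually ≥ 90° apart, so window means
separate postures linearly — the property behind the near-perfect posture
accuracies, and a tested invariant (> 45° pairwise after jitter).

**Behaviors** add dynamics (defaults, all in g, all configurable):
resting 0.01 slow drift with 0.01 noise; ruminating a 1.0 Hz sinusoid of
0.05 (regular jaw cycles, verified by an FFT peak test); feeding a 0.8 Hz
sinusoid of 0.15 plus Poisson bursts at 0.3 Hz (feed pulling); standing
still pure 0.02 noise; moving 0.3 impulse trains at 1 Hz — a walking step
rate consistent with the ethogram's definition of moving as at least a
step every 10 s. Sinusoids ride mainly on the fore–aft y axis, bursts on x
and y. The ethogram constrains pairs: recumbent cows only rest or
ruminate; feeding, moving and standing still require standing.

**Sessions** concatenate bouts with a ~1.5 s crossfade of the static
component at posture changes, and flag spans centered on bout boundaries
as `AMBIGUOUS` so that their overall share hits the schedule's
`ambiguous_fraction` (default 0.07, the removal rate of the motivating
dataset). The returned ground-truth intervals cover exactly the
non-ambiguous spans, so `apply_annotations()` on them reproduces the trace
labels — a tested round trip. `default_schedule()` fixes a 16-bout,
90-minute mixture whose time shares follow the published time budget
(≈60% standing / 40% lying; resting ≈31%, feeding ≈18%, moving ≈18%,
standing still ≈20%, ruminating ≈12% split between postures).

**What the simulator does not model** — and therefore what passing tests
do and do not show: no diurnal structure, no inter-animal variation, no
sensor drift or harness slip, no behaviors outside the five-class
ethogram, and dynamics far cleaner than real flank signals. End-to-end
recovery on synthetic sessions (posture ≥ 0.95, behavior ≥ 0.70 for a
seeded random forest; in practice both are ≈1.0) demonstrates that the
pipeline's plumbing — labeling, exclusion, featurization, pruning,
normalization, fitting, scoring — is correct and that the posture ≫
behavior difficulty ordering has the expected direction. It says nothing
about accuracy on real animals; the only real-data quantities the package
reproduces are the published confusion-matrix-derived panels above.

## Numerical and design notes

- All randomness in a pipeline run derives from one seed with fixed
  per-stage offsets (simulation, split, per-model fits); two runs with the
  same seed produce byte-identical prediction files.
- Timestamp arithmetic at 0.01 s resolution uses a 1 µs guard when testing
  half-open coverage and interval adjacency, so floating-point noise never
  flips a boundary sample.
- Greedy pruning ties (equal mean absolute correlation) drop the
  first-indexed member, making the result order-stable.
- The training size is `round(n × train_fraction)`.
- Problem sizes in tests and the acceptance script: sessions of 15–120
  simulated minutes (≈4,500–36,000 samples, up to ≈2,600 windows), chosen
  to exercise every code path at comfortable interactive runtimes; the
  window-arithmetic check runs on a full-length 456,730-sample stream
  because it is the one quantity whose value depends on stream length.

## Known limitations

- The simulator's separability makes synthetic behavior classification
  easier than the real task; synthetic accuracies must not be read as
  expected field performance.
- The random split pools windows from overlapping strides, so adjacent
  train/test windows share up to 27 samples; published protocols for this
  design do the same, but a deployment-grade evaluation should split by
  animal or by time block.
- `read_sensor_csv()` handles naive local timestamps only (no time zones,
  no DST) and requires strictly increasing times.
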