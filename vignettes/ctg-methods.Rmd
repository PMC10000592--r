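---
title: "Stage-aware CTG classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-aware CTG classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgkit)
```

## The problem

A cardiotocograph records the fetal heart rate (FHR, bpm) together with
the maternal uterine contraction pressure (UCP). Clinicians read the
trace for the classic warning signs of fetal hypoxia — loss of baseline
variability, recurrent late decelerations, a sinusoidal rhythm — and
grade it Normal (1), Suspicious (2) or Pathological (3). Automated
grading has two stubborn difficulties. First, the labels themselves are
soft: the Suspicious class is a clinical gray zone with poor
inter-observer agreement, so any supervised model inherits annotation
noise. Second, the first stage of labor (cervical dilation) and the
second (active pushing) produce very different dynamics — contractions
and decelerations become more frequent and deeper in stage 2 — so the
meaning of a feature changes with the stage. `ctgkit` implements the
full pipeline with the stage carried explicitly as a feature, and ships
a synthetic generator so every stage of the pipeline can be validated
against known ground truth rather than against private clinical labels.

## The synthetic generator

`generate_record()` composes an FHR trace as

> baseline level + slow drift + band-limited variability noise +
> summed event deflections, clipped to [50, 220] bpm,

and a UCP trace as a resting tonus of 10 units plus raised-cosine
contraction bumps (amplitude 30–50, one minute long) at the configured
period. Events use the canonical textbook morphologies that motivate the
clinical typing rules: accelerations and early decelerations are
raised-cosine bumps (gradual onset, symmetric); late decelerations are
raised-cosine bumps whose nadir lags the nearest contraction peak by
`late_lag_s` (default 40 s); variable decelerations are piecewise-linear
V shapes whose onset-to-nadir time (~10 s) is deliberately inside the
30-second "abrupt" band. Every placed event is written to the ground
truth with its exact start/extremum/end samples, which is what the
detector scoring in the tests and the acceptance script compare against.

Parameter choices worth spelling out:

* **Sample rate 4 Hz.** The de-facto convention for archived CTG traces;
  every duration parameter is specified in seconds and converted.
* **Variability noise.** Gaussian white noise low-pass filtered at
  0.5 Hz (2nd-order Butterworth, forward–backward) and rescaled to the
  configured standard deviation. Real beat-to-beat variability is not
  Gaussian and its spectrum is not flat-then-cut; this is an explicit
  stand-in. It does reproduce the two properties the estimators rely on:
  segment-level standard deviation equal to the configured value, and
  multiple baseline crossings per minute. Passing tests therefore
  demonstrate correct recovery of *these* statistics, not robustness to
  every artefact of clinical traces (maternal-heart-rate capture, probe
  dropout correlated with contractions, quantized storage).
* **Gaps.** Missing signal is a boolean mask, laid down in ~30-second
  runs until the requested fraction of samples (≤ 50%) is flagged. A
  mask, not sentinel values, keeps all downstream arithmetic honest.
* **Class recipes** (`generate_cohort()`): Normal records get moderate
  variability (SD 5–7.5 bpm), 2–5 accelerations and at most two early
  decelerations; Suspicious records get reduced variability (2.5–5 bpm),
  mild tachy- or bradycardia and 2–4 variable decelerations;
  Pathological records get near-absent variability (0.3–1.8 bpm) and
  recurrent late decelerations, or (20% of them) a sinusoidal pattern.
  Stage-2 cohorts shorten the contraction period to 70–110 s, deepen
  decelerations by 10 bpm and make them more numerous, and shorten the
  record to 20 min (stage-2 recordings are capped at 30 min). Event
  durations were chosen so that the morphology survives detection:
  a gradual deceleration must keep its detected onset-to-nadir above
  30 s after noise has eaten the shallow tails of the bump, which needs
  total durations of roughly 90 s and depths ≥ 25 bpm at these noise
  levels.
* **Raters.** Six simulated annotators each report the true class with
  probability `concordance` and otherwise an *adjacent* class (1↔2,
  2↔3) — confusions across the full severity range are clinically
  implausible. The majority vote (`aggregate_annotations()`) breaks ties
  toward the more severe class: when annotators split evenly, escalating
  is the conservative obstetric default. Both choices are configurable
  in principle but fixed here and exercised exhaustively in the tests
  (all 3^6 patterns against a brute-force oracle).

## Baseline, variability and events

**Baseline.** `estimate_baseline()` works in 10-minute windows with
3 minutes of overlap (7-minute step, final window anchored to the end of
the record). Within a window the initial "virtual" baseline is the mode
of the valid samples binned at 1 bpm — a level estimator that ignores
event excursions better than a mean. Iteration then alternately excludes
samples further than 10 bpm (the event envelope) from the current
estimate and recomputes the median of the rest, until the change is
below 0.5 bpm or 20 iterations. A window's value is accepted only when
the samples within the envelope of the final estimate total more than
120 s — not necessarily contiguous — otherwise the window is
*unidentifiable* and reported as such rather than guessed. The envelope,
tolerance and iteration cap are arguments; the defaults were fixed
before any cohort-level evaluation and are the values the acceptance
run uses.

**Variability.** The record is cut into discrete 10-minute slices, each
into 1-minute segments. A segment has measurable variability only if the
deviation from baseline completes more than one cycle there (more than
two sign changes); a qualifying segment contributes the standard
deviation of the deviation. Segments combine within a slice by
**mean** (default) or by **sum**, and slices average into the record
value. The sum reading multiplies the per-segment SD by the number of
qualifying segments (~10 per slice), which cannot reproduce the
configured noise level and contradicts the recovery behaviour the rest
of the pipeline assumes; the mean is therefore the default and the sum
kept as an option. Undetermined variability (no qualifying segment
anywhere, e.g. a flat trace) is reported as `NA`/`Absent`, never
imputed. The classification bands are the standard ones: Absent
(≤ 0.5 bpm, i.e. undetectable), Minimal (≤ 5), Moderate (5–25], Marked
(> 25).

**Accelerations and decelerations.** Both detectors segment the
baseline-crossing excursions of the deviation series; an excursion may
not bridge a masked run longer than 15 s (shorter gaps are bridged).
Accelerations use the crisp definition: 15 s ≤ duration ≤ 10 min and
peak > 15 bpm above baseline; longer excursions are flagged as baseline
changes. Decelerations are graded fuzzily with trapezoidal memberships —
duration: 0 below 10 s, linear 10→15 s, 1 on [15 s, 10 min], 0 above;
depth: 0 below 10 bpm, linear 10→15 bpm, 1 at ≥ 15 bpm — combined by
minimum and emitted at membership ≥ θ (default 0.5). Any event meeting
the crisp definition grades exactly 1, so on unambiguous events the
fuzzy detector *equals* a crisp detector (a tested equivalence), and the
fuzzy machinery only ever adds borderline events such as a 60-second,
12-bpm dip (membership 0.4, rejected at the default θ, admitted at
θ = 0.3).

**Typing.** Early/late/variable typing is rule-based, standing in for a
trained classifier whose training data (expert-typed events) does not
exist here: onset-to-nadir < 30 s ⇒ variable (the abrupt/gradual
convention); otherwise the nadir is matched to the nearest contraction
peak — within ±15 s ⇒ early, lagging by more than 15 s ⇒ late, no peak
within ±120 s (or a gradual nadir *leading* the peak) ⇒ variable. An
empty contraction log types everything variable and warns. All
thresholds are arguments.

**Sinusoidal pattern.** Screened spectrally on ≥ 20 min of valid
signal: Present when more than half the deviation's spectral power sits
in the 2–5 cycles/min band with an equivalent sine amplitude of
5–15 bpm and no accelerations; less than 20 valid minutes is
Undetermined — a distinct category carried through to the classifier,
since an unassessable record is not evidence of absence.

## Classification harness

`ctg_cv()` is the package's central fitting function. The 11-feature row
is encoded numerically (`encode_ctg_features()`): ordered categories
ordinally (variability class 0–3), unordered ones one-hot with
Undetermined as its own indicator, counts and levels as-is. Folds are
stratified per class (shuffled round-robin), which guarantees per-fold
class shares within one sample of the global shares and every class in
every fold — plain random folds can starve the smallest class at these
cohort sizes. With `smote = TRUE` each training fold is rebalanced to
class parity by SMOTE before fitting; synthetic rows carry a provenance
flag and exist only inside that fold's training set, so the held-out
fold always contains original records only. SMOTE itself interpolates
uniformly between a minority sample and one of its 5 nearest same-class
neighbours; the convex-combination property is asserted per synthetic
row in the tests.

The four classifiers are deliberately standard library models behind one
interface: `randomForest` (500 trees), `e1071::svm` (RBF kernel,
probability output), `nnet` for the perceptron, and bagged `rpart`
trees (25 bootstrap replicates). One deviation deserves a note: the
perceptron is specified in the source design as three sigmoid hidden
layers, but no installed R package fits multi-hidden-layer perceptrons;
`nnet`'s single hidden layer (size 8, logistic units, softmax output,
weight decay 0.01) is the closest standard-library model and behaves
equivalently on these low-dimensional features. Hyperparameters live in
the `hyper` argument. The per-fold metric set is
{Accuracy, TPR, FPR, Precision, Recall, F-Measure, ROC, kappa, RMSE}
(support-weighted one-vs-rest where applicable, macro AUC for ROC, RMSE
on the 1–3 scale), and `fold_metric_correlation()` correlates these
9-vectors between models within each fold, the diagnostic used to judge
whether a fold configuration treats all models alike.

## Evaluation battery

All agreement statistics are computed from the 3×3 confusion matrix or
from any label sequence realizing it (`realize_pairs()`; the statistics
are order-invariant, which is tested). Conventions that needed fixing:

* **Averaging** is support-weighted one-vs-rest by default (macro
  available); under weighting, sensitivity coincides with accuracy.
* **Bland–Altman** uses differences `actual − predicted` (so a positive
  bias means the classifier under-calls severity) and the population
  (n) standard deviation by default, with `n−1` as an option; CIs are
  normal-theory (`se(bias) = sd/√n`, `se(LoA) = sd√(3/n)`). These two
  conventions are what reproduce the reference tables shipped in
  `inst/extdata/`.
* **Chi-squared** is the plain Pearson statistic without continuity
  correction (df = 4 for 3×3), delegated to `stats::chisq.test` and
  verified against a brute-force double loop to 1e-9.
* **Discriminant power** is reported as `Inf` when sensitivity or
  specificity touches 0 or 1 rather than being clamped.
* **KMO** is computed from the anti-image matrix
  `a_ij = −R⁻¹_ij/√(R⁻¹_ii R⁻¹_jj)`; a singular correlation matrix is an
  explicit error (it means a feature is redundant), not a silent
  pseudo-inverse. Bartlett's statistic is
  `−(n−1−(2p+5)/6)·ln det R` on `p(p−1)/2` df.
* **AUC** is one-vs-rest by the rank (Mann–Whitney) formula with
  midpoint tie handling — equivalent to trapezoidal integration of the
  ROC — cross-checked against `pROC` in the tests.
* Report-style rounding is half-away-from-zero (`round_half_away()`),
  matching how the reference tables print; R's default banker's rounding
  differs exactly at the .5 boundaries the limits of agreement land on.

## Problem sizes and determinism

The test suite and the acceptance script run the pipeline at sizes
chosen to make the statistical assertions stable: detector and baseline
properties on 100-record stage-1 cohorts, the end-to-end classifier
comparison on a 300-record stage-1 cohort with 0.9-concordance raters,
and a 150-record stage-2 cohort. Every stochastic step (generation,
rater simulation, folds, SMOTE, model initialization) flows from an
integer seed; identical seeds give bit-identical records and
predictions, which is itself asserted. The synthetic classes are
separable by construction, so cross-validated accuracies near 1 on
clean cohorts say the pipeline is wired correctly — they are ceiling
measurements, not claims about clinical performance.

## Known limitations

* The generator does not model maternal-heart-rate capture, signal
  quantization, transducer artefacts, or physiologically mechanistic
  fetal circulation; gaps are independent of events.
* The noise spectrum of real FHR variability is not characterized here;
  the band-limited Gaussian choice is a documented stand-in.
* Deceleration typing is rule-based; borderline gradual/abrupt onsets
  (near 30 s) are the dominant source of typing error on noisy traces.
* Whether the 40-minute selection rule counts wall-clock or mask-valid
  minutes is ambiguous in clinical practice; `select_record()` uses
  wall-clock duration of the stage-1 span.
* Frequency-domain variability indices (LF/HF), pH prediction and
  denoising are out of scope.
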