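---
title: "Classifying single-lead ECG rhythm: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying single-lead ECG rhythm: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Atrial fibrillation (AF) is the most common sustained arrhythmia and is
frequently silent; screening relies on long-term single-lead ECG
monitoring by wearable patches. `ecgaf` implements the analysis side of
such a monitor: it classifies a short (nominally 30 s) single-lead ECG
segment into one of four classes — **Normal** sinus rhythm, **AF**,
**Other** arrhythmia, or **Noisy** — using a hand-crafted 31-dimensional
feature vector and a gradient-boosted decision-tree classifier, with
importance-based feature selection down to the 17 most informative
features.

Electrophysiologically, AF shows three signatures a feature detector can
target: irregularly irregular RR intervals, absent P waves, and a
fibrillatory (f-wave) baseline. The feature set covers the first two
directly; the third is only emulated in the synthetic generator (no
frequency-domain f-wave feature is computed — the Lorenz-plot and
entropy features carry the discriminative load).

```{r, eval = FALSE}
library(ecgaf)
out <- generate_ecg(verification_preset())
extract_features(out$recording)[c("af_evidence", "r_amplitude_mV_E")]
```

# Pipeline

1. **Preprocessing.** Zero-phase band-pass Butterworth filtering
   (defaults 0.5–40 Hz, order 3), R-peak detection, RR and dRR interval
   construction.
2. **Feature extraction.** 31 named scalars per segment (below).
3. **Classifier training.** Gradient-boosted trees, 20-fold stratified
   cross-validation with early stopping on the multiclass Matthews
   correlation coefficient (MCC).
4. **Feature selection.** Features ranked by ensemble importance; the
   top 17 kept.
5. **Re-training.** A final model on the selected features, with the
   iteration count fixed to the median per-fold best iteration.

Each stage is exposed both as R functions and as a subcommand of the
`inst/cli/ecgaf.R` script (`simulate`, `prepare`, `features`, `train`,
`evaluate`, `predict`), handing off plain CSV/JSON artifacts so any
stage can be audited or re-run in isolation.

# Preprocessing choices

The filter band is a deliberate monitoring-band compromise: the 0.5 Hz
high-pass corner removes baseline wander without attenuating P waves
(which the morphology features need), and the 40 Hz low-pass corner
suppresses mains and muscle noise while retaining QRS energy. The filter
is applied forward-backward so fiducial timing is not shifted.
Zero-phase application squares the magnitude response, which the filter
tests account for analytically.

R-peak detection is a Pan–Tompkins-style energy detector: a 5–15 Hz
band-pass isolates QRS energy, a squared central-difference derivative
is integrated over a 150 ms moving window, and candidate peaks are
accepted against a running signal/noise threshold
(`thr = npk + 0.25 (spk − npk)` with exponential updates) under a 200 ms
refractory period. All thresholds are relative, so detection is
invariant to amplitude scaling. Detections are refined to the signed
extremum of the input signal within ±100 ms; if the median refined
extremum is negative the lead polarity is inverted first
(chest-patch leads may present inverted QRS complexes). The first and
last 0.5 s are excluded from the search, so a beat placed closer to the
edge than that is invisible to the detector by construction. Whether
detection should run on the filtered or the raw signal is an open
choice; this package always detects on the filtered signal, which is
also what feature extraction delineates.

# The 31 features

**AF features (3).**

* `af_evidence`: the dRR Lorenz plot — the scatter of consecutive
  (dRR[i], dRR[i−1]) pairs — is histogrammed with 40 ms bins over
  ±600 ms (outliers clipped to edge bins) and partitioned into 13
  regions: the origin box (both coordinates within ±80 ms), four axis
  strips, the two main-diagonal quadrants, and the two anti-diagonal
  quadrants each split into an anti-diagonal band plus two off-band
  wings. The score is
  `IrregularityEvidence − OriginCount − 2·PACEvidence`:
  occupied-bin count outside the origin, minus the points at the
  origin, minus twice the (floored-at-zero) excess of points in the
  ectopy-pattern regions — anti-diagonal bands and vertical strips,
  where the short–long alternation of premature beats with compensatory
  pauses concentrates — over the remaining outer regions. Sustained AF
  scatters points over many bins (strongly positive); regular rhythm
  piles them at the origin (negative); bigeminy-like ectopy is
  discounted. The 13-region geometry follows the Lorenz-plot AF
  detector tradition; the precise region masks are this package's
  documented instantiation, and the tested contracts are behavioural
  (sign, ordering, conservation, stump separability).
* `shannon_entropy_drr`: `−Σ p ln p` over a fixed 16-bin histogram of
  dRR clipped to ±0.5 s. The binning is fixed (not data-adaptive) so
  values are comparable across recordings.
* `ks_statistic`: two-sample Kolmogorov–Smirnov statistic between the
  recording's normalised dRR sample (dRR divided by the median RR) and
  a reference distribution of pooled normalised dRR values from
  AF-labelled training recordings. How such a reference is obtained is
  a free design choice; pooling the training AF segments is the
  simplest defensible option, and the reference is serialised with the
  model bundle so prediction reproduces training-time features exactly.
  When no AF training data are available the package falls back to a
  reference built from its own seeded synthetic AF corpus
  (`default_ks_reference()`).

**Morphology features (20).** Ten kinds — QRS duration, PR, QT, QS
intervals; ST, P, Q, R, S, T amplitudes — each measured by two
estimation variants: `E` delineates the **average beat** (per-sample
mean of R-aligned windows, [−0.3, +0.5] s), `O` delineates **every
individual beat** and takes the per-kind median. Two variants per kind
mirror the common practice of running two independent delineation
toolchains and letting the classifier weigh both estimates; here both
are internal, removing external Fortran/C dependencies while preserving
the two-estimates-per-kind structure. Fiducials: Q = minimum in
[−60, 0] ms before R; S = minimum in [0, 80] ms after; QRS onset/offset
= where the absolute slope falls below 10% of the QRS maximum scanning
outward from Q/S; P peak = maximum in [−250, −80] ms; T peak = extremum
of larger magnitude in [+120, +400] ms; T end = T peak + 80 ms; ST
amplitude at QRS offset + 60 ms. Amplitudes are measured against the
isoelectric level (mean of the [−90, −70] ms window). Note one
systematic difference between the variants on AF signals: the coherent
average suppresses the incoherent fibrillatory baseline, so the `E`
P amplitude goes to ~0, while the per-beat maximum cannot fall below the
f-wave crest, so the `O` P amplitude floors at roughly the f-wave
amplitude. Both behaviours are informative and the classifier sees both.

**RR features (5).** Median RR; the index of arrhythmia — the count of
beats abnormal under four knowledge-based conditions on three
consecutive RR intervals and their mean `m`: premature-plus-pause
(`rr[i] < 0.85 m` and `rr[i+1] > 1.15 m`), dropped beat
(`rr[i] > 1.5 m`), ectopic burst (`rr[i] < 0.4 s`), abrupt change
(`|rr[i] − rr[i−1]| > 0.3 m`) — plus three conventional RR statistics
(mean RR, RMSSD, pNN50) that complete the feature set to its stated
dimensionality; these three are flagged `gap_fill` in
`feature_manifest()` because they are this package's choice of
additional RR descriptors rather than documented originals.

**Noise features (3).** Mean pairwise Pearson correlation of all QRS
windows ([−60, +80] ms); the signal quality index (fraction of beats
whose isoelectric-window peak-to-peak is below 20% of the beat's R
amplitude — the 20% threshold is this package's concrete choice); and
the Q-R smoothness index, the count of local maxima in the
first-difference sequence of the average beat's upstroke (QRS onset to
R), which is 1 for a clean concave upstroke and grows with
high-frequency corruption.

**Imputation is total.** Any failure path (no beats, too few beats,
delineation failure) imputes: intervals, amplitudes and scores to 0,
`ks_statistic` to 1. Failure modes are noise-like, and these defaults
push the segment toward the Noisy class rather than fabricating
physiology. Every code path returns exactly 31 finite values.

# Classifier

The boosting backend is xgboost. Defaults: learning rate 0.1, up to 276
iterations, early-stopping patience 20, depth 8, L2 leaf regularisation
3, multiclass softmax objective, multiclass MCC as the validation
metric, fixed seed, single-threaded (deterministic). Two configured
options — bagging temperature 0.7 and random strength 0.2 — are
Bayesian-bootstrap/score-perturbation controls that xgboost does not
implement; they are retained in the hyperparameter object, announced at
training time, and recorded in the model bundle's `backend_gaps` so the
gap is never silent. Newton (second-order) leaf estimation is xgboost's
native behaviour.

Cross-validation uses **stratified** folds rather than plain random
ones: with a rare Noisy class, plain 20-fold splitting can leave folds
without any member of a class, which destabilises both the validation
MCC and early stopping. Each fold validates exactly one model; the
final re-training on the selected features uses the median per-fold
best iteration with no further early stopping (re-using the held-out
folds for stopping the final model would leak). The cross-validation
models are discarded after their best-iteration and score statistics
are collected; only the re-trained final model is kept.

Class imbalance is deliberately not reweighted.

`predict()` renormalises the backend's float32 softmax rows so
probabilities sum to 1 exactly.

# The synthetic generator

The generator replaces a hardware patient simulator for testing, and
its defaults are the bench verification settings: the
`verification_preset()` is 30 s of normal sinus rhythm at 80 BPM with
1.0 mV R amplitude at 250 Hz.

* **NSR**: Gaussian template waves (P at −170 ms, 0.15 mV default;
  Q/S deflections at −10%/−15% of R; R with 13 ms width; T at +300 ms,
  30% of R) placed at RR intervals drawn from a truncated normal
  (floor 0.3 s, cap 2 s) with mean `60/heart_rate_bpm` and a small
  coefficient of variation (default 0.03).
* **AF**: the P wave is removed (enforced by spec validation), RR
  intervals are drawn i.i.d. with CV ≥ 0.15 (default 0.25), and a
  0.05 mV sinusoid whose frequency random-walks within 4–9 Hz emulates
  the fibrillatory baseline. An i.i.d. truncated normal is used rather
  than an atrioventricular-node conduction model because only RR
  irregularity statistics are consumed downstream.
* **NOISE**: white noise (default SD 0.3 mV) plus 50 Hz mains and slow
  baseline wander, with no coherent beats — exercising all three noise
  features.

`simulate_corpus()` draws per-recording physiology from ranges a
monitoring study would consider realistic: NSR 55–100 BPM with RR CV
0.01–0.07; AF 70–140 BPM with RR CV 0.18–0.35; R amplitudes 0.6–1.5 mV;
P amplitudes 0.08–0.25 mV.

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: realistic QRS morphology variation and
ectopic beats, respiratory/autonomic HRV structure, atrial flutter and
the whole Other class, electrode-motion artifacts that mimic QRS, and
the low-amplitude noise floor of dry-electrode wearables. The
end-to-end benchmark (1000 synthetic segments, 80/20 split) is a
desk-scale correctness check of the pipeline's machinery and of class
separability under the stated conditions; scores on it say nothing
about clinical performance.

# Data handling

WFDB records (header/signal/annotation; signal formats 212 and 16) and
MATLAB v4 Challenge-style records are read by small internal parsers,
with samples converted to mV via the recorded gain and baseline. Long
annotated records are cut into consecutive non-overlapping 30 s windows
(trailing partial windows discarded — every feature assumes a full
window of context); each window takes the rhythm code covering the
majority of its duration (ties to the earlier code), mapped AFIB→AF,
AFL→Other, J→Other, N→Normal, and windows whose majority code is
unmapped are dropped. The majority rule is this package's deterministic
choice for mixed-rhythm windows; published per-class segment counts for
the source databases may therefore not be exactly reproducible from
this rule alone. Records from 250 Hz and 300 Hz sources are *not*
resampled to a common rate: every feature is computed in seconds and
millivolts and is sampling-rate-agnostic. Train/test splitting is
label-stratified at a 0.2 test fraction and seed-deterministic.

# Numerical and degenerate-input conventions

* Sample indices are 1-based in R; segmentation windows are half-open.
* Entropy bins, Lorenz bins and all fiducial windows are fixed in
  physical units, never adaptive.
* F1 of a class with no true and no predicted members is defined as 1;
  the overall F1 averages Normal, AF and Other only (the Noisy class is
  scored but excluded, following the Challenge convention).
* The multiclass MCC uses the covariance form; degenerate denominators
  (all predictions one class) return 0.
* Binary AF sensitivity with no true AF is reported as `NA`, not 0.
* All-zero or too-short recordings yield an empty peak list or an
  insufficient-beats condition, which feature extraction converts into
  the imputation defaults.

# Problem sizes used in the shipped checks

The test-suite benchmark uses 1000 synthetic 30 s segments (430 Normal,
380 AF, 190 Noisy; seed fixed) with an 80/20 stratified split, 20-fold
cross-validation and top-17 selection — large enough for stable scores,
small enough to run routinely on one CPU. The importance-curve helper
defaults to 5-fold validation per point since only the plateau shape
matters there.

# Known limitations

* The Other class has no synthetic generator, so end-to-end recovery is
  demonstrated on three of the four classes; Other-class behaviour is
  exercised only at the metrics and IO level.
* The per-beat (`O`) morphology variant floors at the noise/f-wave
  amplitude for small waves (see above).
* The AF-evidence region masks are a faithful-in-spirit, documented
  reconstruction, not a bit-exact port of any published detector.
* The WFDB/MAT parsers implement the subsets of those formats the
  supported databases use (formats 212/16, v4 int16 matrices), not the
  full specifications.
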