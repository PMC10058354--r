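---
title: "Detecting functional arm use from a wrist-worn IMU: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting functional arm use from a wrist-worn IMU: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearfu)
```

## The measurement problem

Clinicians treating people with an upper-limb amputation (or other unilateral
upper-extremity impairment) want to know how much the affected limb is
actually *used* outside the clinic: movements that contribute to activities
of daily living — reaching, grasping, gesturing — as opposed to arm swing
during gait or rest. A single wrist-worn inertial measurement unit (IMU)
recording three-axis linear acceleration and three-axis angular velocity at
200 Hz is cheap and unobtrusive; the analysis problem is to turn that
six-channel stream into a per-recording estimate of the *percentage of time
in functional use*.

`wearfu` implements a block-classification pipeline for this problem:

1. **Ground truth** comes from frame-by-frame video annotation by up to
   three annotators using a five-level coding scheme (FAABOS): unknown (-1),
   no activity (0), nonfunctional movement (1), nontask-related functional
   (2), task-related (3). Codes are fused by per-frame majority (no
   majority, or a majority of *unknown*, excludes the frame) and collapsed
   to binary labels: {2, 3} functional, {0, 1} nonfunctional, -1 excluded.
2. **Segmentation** cuts the stream into blocks, either fixed 800-sample
   blocks (4 s at 200 Hz) or variable-length blocks produced by a
   change-point detector (below).
3. **Features**: each block yields 21 numbers — per-channel histogram
   entropy, mean and variance, plus the zero-lag correlation of the three
   axis-matched accelerometer/gyroscope pairs.
4. **Classification**: a seeded Random Forest (100 trees, 4 features per
   split) labels each block functional or nonfunctional, evaluated by
   intra-subject 10-fold cross-validation and by inter-subject
   leave-one-subject-out, with chunk-size-weighted accuracy.
5. **Outcome**: percent of (block) time predicted functional, compared with
   the annotation-derived ground truth, and nonparametric summaries
   (median/range, Mann-Whitney U between groups, Wilcoxon signed-rank
   between methods).

## The change detector behind variable segmentation

The variable method grows a segment until the data look different from what
follows. At candidate boundary $b$ the trailing 2000 samples $A$ of the
current segment are compared with the next 2000 samples $B$ using the
two-sample Hotelling statistic

$$T^2 = \frac{mn}{m+n}\, \bar{d}^{\top} S^{-1} \bar{d},$$

where $\bar d$ is the difference of the six-channel means and $S$ the pooled
sample covariance. If $T^2$ exceeds a threshold, the segment is closed at
$b$ and a new one starts there; otherwise $b$ advances by 600 samples. The
first block can therefore be 2000 samples, or 2600, 3200, … ; a terminal
remainder shorter than 2000 samples is attached to the last block so the
blocks always partition the recording. Because both windows always have
2000 rows, $T^2$ at a boundary is a pure function of $b$, which the
implementation exploits by computing window moments from cumulative sums.

Two points in this design were genuinely open:

* **Direction of the test.** $T^2$ is large when the windows differ, so a
  change is declared when the statistic *exceeds* the threshold. (A
  thresholded p-value would point the other way; thresholding the statistic
  itself is the numerically simpler, equivalent choice once the threshold is
  calibrated, and the calibration procedure is agnostic to the direction.)
* **What "the segment" means in the comparison.** The growing segment is
  represented by its trailing 2000 samples rather than its whole extent, so
  both windows keep a fixed size and the statistic keeps a fixed null scale
  regardless of how long the segment has grown.

**Threshold calibration.** The threshold is not a fixed constant; it is
calibrated on recordings with known transition times to the smallest
detector strictness that still finds 80% of true transitions: candidate
thresholds are swept over the observed boundary statistics and the *largest*
threshold whose pooled true-positive rate reaches `target_tpr` (default
0.80) is kept. A transition counts as detected when some declared boundary
lies within one shift (600 samples, i.e. 3 s) of it. Choosing the largest
qualifying threshold suppresses early firing: a window that merely straddles
a transition sees a diluted mean difference, and a strict threshold defers
the boundary to a candidate nearer the true change. The true-positive rate
is defined per transition, not per block; with ~30 transitions in a
10-minute recording a single recording's TPR has a standard error of about
0.07, so calibration and evaluation should pool transitions across
recordings.

**Covariance regularization.** On near-constant rest data the pooled
covariance can be numerically singular, so $S$ is ridged with
$\varepsilon \cdot \overline{\mathrm{diag}(S)} \cdot I$,
$\varepsilon = 10^{-6}$ by default. The ridge is relative, so the statistic
keeps its affine invariance on well-conditioned data (verified by test). If
both windows are exactly constant the statistic is defined as 0.

## Features

* **Entropy.** Histogram Shannon entropy with 16 equal-width bins spanning
  the block's own range, in bits (0 for a constant block, at most
  $\log_2 16 = 4$). Binning per block makes the feature invariant to affine
  rescaling — it measures signal *complexity*, not amplitude. The bin count
  is configurable; 16 is a common choice for 4-second IMU blocks and keeps
  expected counts per bin well above 1 at the block sizes used here.
* **Mean and variance** per channel (variance with the $n-1$ denominator)
  carry posture (gravity projection) and intensity.
* **Cross-correlation.** Zero-lag Pearson correlation of the three
  axis-matched pairs (ax–gx, ay–gy, az–gz), 3 features rather than all 9
  pairs; with 21 features, the forest's 4-features-per-split heuristic is
  close to the usual $\sqrt{p}$ rule. If either channel has zero variance
  in a block the correlation is defined as 0.
* **Block size** is attached to each vector as metadata for size-weighted
  accuracy and time-share estimates; it is *not* a classifier input, so
  fixed- and variable-method feature spaces are identical.

## Block ground truth, mixed blocks, and a revised purity default

A block's ground truth is the class holding more than 50% of its
non-excluded samples; an exact tie goes to nonfunctional (the conservative
non-use class, since neither class strictly exceeds half). A block in which
half or more of the samples are excluded is itself excluded. The largest
class share among non-excluded samples is reported as the block's *purity*.

The fixed method classically ignores *mixed* blocks — blocks containing
both classes — in both training and accuracy scoring, because their label is
ill-defined. Taken literally ("purity < 1"), this rule interacts badly with
annotation noise: when annotators occasionally err on isolated frames, a
consensus error on even one frame makes an otherwise homogeneous 800-sample
block "mixed". Under this package's default annotator-noise model that
discards 10–15% of genuinely homogeneous blocks *at random*, which leaves
accuracy almost untouched but visibly destabilizes the functional-use
percentage (the surviving functional share becomes a random subsample). The
default cutoff is therefore `purity_cutoff = 0.95`: a block is mixed when
it is *structurally* mixed (contains a class transition; such blocks have
purity roughly uniform on (0.5, 1)), while near-pure blocks carrying an
isolated annotation error keep their majority label. The observed purity
distribution is strongly bimodal, so the exact cutoff matters little within
(0.95, 1); the strict rule remains available via `purity_cutoff = 1`.
The variable method uses all majority-labelled blocks, mixed or not.

## Classifier and protocols

The Random Forest uses 100 trees, unlimited depth, no backfitting, 4
features per split, and a fixed seed (123) set immediately before fitting,
so refits are bit-reproducible. Forests from different libraries cannot be
expected to agree tree-for-tree; the contract here is the stated
hyperparameters plus seeded determinism, and the fit is delegated to the
`randomForest` package.

Intra-subject evaluation partitions one subject's usable blocks into 10
uniform random folds (a separate protocol seed; unstratified, since no
stratification is specified for this design — with 100+ blocks per subject
and class shares between 20% and 80%, degenerate folds are not a practical
concern). Inter-subject evaluation trains on the pooled raw blocks of all
other subjects — no per-subject normalization, which is exactly why
between-subject differences in mounting and signal scale make it the harder
protocol. Control and amputee groups are evaluated separately, and the
driver refuses mixed-group cohorts. Accuracy is chunk-size weighted
(equivalent to plain accuracy for fixed blocks). Functional-use percent is
the size-weighted share of blocks labelled functional among non-excluded
blocks, computed from the same block set that receives predictions.

## Group statistics

Summaries are medians with ranges. The Mann-Whitney U test compares
independent groups: the p-value is exact (null U distribution) when there
are no ties and $n_A + n_B \le 20$, otherwise a tie-corrected normal
approximation *without* continuity correction. The Wilcoxon signed-rank
test compares paired methods: zeros are dropped; the p-value is exact for up
to 25 tie-free pairs, otherwise (or on request, `exact = FALSE`) the
tie-corrected normal approximation without continuity correction. Each
result reports which method produced it, since at these sample sizes the
exact and approximate conventions can differ noticeably and published
analyses vary in which they use.

## The synthetic cohort: what it emulates and what it does not

Real recordings of this kind are not publicly available, so the package
ships a generator that emulates their structure well enough to exercise
every pipeline stage against a known truth:

* **Semi-Markov regimes.** Subjects alternate between rest, gait and
  functional states with lognormal dwell times (mean 20 s, log-sd 0.35) and
  a configurable transition matrix — explicit dwells rather than a
  per-sample Markov chain, so segments are long relative to the 2000-sample
  probe and variable segmentation is meaningful.
* **State signatures.** Each state has its own wrist orientation, so the
  accelerometer mean (gravity projection) shifts by order 1 g between
  states — this is what a mean-based change detector keys on, and it is the
  physically realistic carrier of posture information. Rest is low-variance
  noise; gait adds a ~1 Hz arm-swing sinusoid with a first harmonic,
  gyroscope-dominant; functional movement adds irregular smooth bell-shaped
  velocity pulses with randomized amplitude and width plus broadband noise,
  giving the highest variance and entropy.
* **Per-subject idiosyncrasies.** Each subject gets multiplicative channel
  gains (log-sd 0.15), a gait frequency factor (0.85–1.15), and a
  device-mounting rotation (uniform ±30° about the forearm axis plus a
  small random tilt, applied identically to both sensor triads). Mounting
  variation is the dominant realistic source of between-subject feature
  shift for wrist devices; it leaves within-subject classification easy
  while making pooled inter-subject training genuinely harder, and it does
  not affect the change detector, whose statistic is invariant under
  common affine channel maps.
* **Noisy annotators.** Three simulated annotators code 30 Hz video frames
  from the true state sequence (rest→0, gait→1, functional→3), each
  independently misplacing every state boundary by up to ±2 frames and
  replacing each frame's code with a uniformly random other code with
  probability 0.05. With majority fusion this leaves well under 2% of
  samples excluded as unknown, the scale reported for human annotators in
  comparable studies.

What the generator does *not* model: biomechanically realistic prosthesis
dynamics, device-type differences, nontask-related functional movement as a
distinct generating state (FAABOS code 2 appears only through annotator
noise), sensor drift, or irregular sampling. Passing the synthetic
acceptance checks therefore demonstrates that the pipeline recovers what it
is designed to recover under controlled regime-switching conditions — not
that real amputee recordings would yield the same accuracy.

## Problem sizes and numerical conventions

The test suite and acceptance script use 4-subject cohorts of 10-minute
recordings at 200 Hz (120 000 samples, ~150 fixed blocks and ~30 state
transitions per subject), sizes at which every quantity of interest is
measurable in seconds of compute while keeping binomial noise on rates
acceptably small (pooled TPR is estimated from ~120 transitions). All
intervals are 0-based and half-open; a boundary sample belongs to the later
frame/block. Sampling is assumed uniform: the `t` column of an IMU CSV is
validated as strictly increasing and then discarded, and permuted files are
rejected rather than reordered. Channel units are carried opaquely (device
units); no calibration or unit conversion is applied anywhere, which is safe
because every feature is computed per channel and per block.

## Known limitations

* The calibrated detector's TPR sits by construction near its 0.80 target;
  on a single new recording the realized TPR can fall several points on
  either side. Pool transitions across recordings before interpreting it.
* Fixed-method functional-use estimates inherit a structural bias from
  discarding boundary blocks; with 20 s mean dwells and 4 s blocks this is
  a few percentage points, and it grows as dwells shorten.
* The variable method's blocks (≥ 2000 samples) yield roughly a tenth as
  many feature vectors as the fixed method, so its forests train on much
  less data — the same trade-off that motivates comparing both methods.
* Exact Mann-Whitney/Wilcoxon p-values are unavailable under ties; the
  normal-approximation convention (tie-corrected, no continuity correction)
  is then reported and flagged in the result.
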