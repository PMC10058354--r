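# wearfu

Detecting **functional arm use** from a single wrist-worn inertial sensor.

Rehabilitation after an upper-limb amputation aims to get the prosthetic
limb used in everyday activities, but there is no practical way to measure
that use outside the clinic. A wrist IMU recording three-axis linear
acceleration and three-axis angular velocity at 200 Hz can be worn all day;
`wearfu` turns such recordings into an estimate of the **percentage of time
the limb is in functional use** (reaching, grasping, object manipulation) as
opposed to nonfunctional movement (arm swing during gait, rest). The
intended users are movement-analysis and rehabilitation researchers working
with wrist-worn sensor data and frame-coded video ground truth.

## Method

Ground truth comes from per-video-frame FAABOS codes by up to three
annotators (−1 unknown, 0 no activity, 1 nonfunctional, 2 nontask-related
functional, 3 task-related), fused by per-frame majority and collapsed to
binary labels ({2,3} → functional, {0,1} → nonfunctional, −1 → excluded).
The stream is cut into blocks in one of two ways:

* **fixed** — consecutive 800-sample blocks (4 s at 200 Hz); blocks whose
  ground truth mixes both classes are excluded from training and scoring;
* **variable** — a block-growing change detector: the trailing 2000 samples
  of the current segment are compared with the next 2000 samples by the
  two-sample Hotelling statistic

  $$T^2 = \frac{mn}{m+n}\,\bar d^{\top} S^{-1}\,\bar d ,$$

  ($\bar d$ = difference of channel means, $S$ = pooled covariance). If
  $T^2$ exceeds a threshold — calibrated to an 80% true-positive rate on
  recordings with known transitions — the segment closes; otherwise the
  boundary candidate advances by 600 samples.

Each block yields 21 features (per-channel histogram entropy, mean,
variance; zero-lag correlation of the three axis-matched accel/gyro pairs)
classified by a seeded Random Forest (100 trees, 4 features per split,
seed 123). Evaluation uses intra-subject 10-fold cross-validation and
inter-subject leave-one-subject-out with chunk-size-weighted accuracy, and
cohorts are summarized as medians (ranges) with Mann-Whitney U and
Wilcoxon signed-rank tests.

Because real recordings of this kind are not public, the package includes a
regime-switching synthetic generator (rest / gait / functional states with
state-specific wrist orientation and dynamics, per-subject mounting rotation
and gains, and noisy simulated annotators) so the whole pipeline is testable
against known truth. See the methods vignette
(`vignettes/functional-use-detection.Rmd`) for the full design rationale.

## Worked example

```r
library(wearfu)

cohort <- generate_cohort(generator_config(duration_s = 600),
                          n_subjects = 4, cohort_seed = 42)
cohort[[1]]
#> <synthetic_subject> synth01 (control): 120000 samples, 31 transitions, true FU 36.8%

datasets <- lapply(seq_along(cohort), function(i)
  subject_dataset(cohort[[i]], annotator_seed = 100 + i))
names(datasets) <- names(cohort)

res <- evaluate_cohort(datasets, method = "fixed")
res$per_subject[, c("subject", "acc_intra", "acc_inter",
                    "fu_truth", "fu_intra", "fu_err_intra")]
#>   subject acc_intra acc_inter fu_truth fu_intra fu_err_intra
#> 1 synth01         1         1     36.9     35.9        0.991
#> 2 synth02         1         1     38.2     35.4        2.735
#> 3 synth03         1         1     34.3     31.2        3.078
#> 4 synth04         1         1     30.0     27.9        2.042
```

Per subject: `acc_intra` / `acc_inter` are the block classification
accuracies under the two protocols (here the synthetic regimes are fully
separable within subjects); `fu_truth` is the annotation-derived percent of
time in functional use and `fu_intra` the classifier's estimate, off by at
most ~3 percentage points (`fu_err_intra`).

Variable-length segmentation needs a calibrated change threshold:

```r
seg <- calibrate_threshold(lapply(cohort, function(s) s$series),
                           lapply(cohort, function(s) s$transitions),
                           segmentation_config())
sprintf("calibrated T2 threshold: %.0f (TPR %.3f)", seg$t2_threshold, attr(seg, "tpr"))
#> "calibrated T2 threshold: 6846 (TPR 0.829)"

head(segment_variable(datasets$synth01$series, seg), 3)
#>   start   end   method
#> 1     0  3800 variable
#> 2  3800  8800 variable
#> 3  8800 14400 variable
```

The calibrated detector finds 82.9% of the cohort's state transitions
within ±600 samples (3 s), just above its 80% calibration target, and block
lengths grow in 600-sample steps from the 2000-sample minimum.

A command-line front end over the same functions is installed with the
package (`inst/cli/wearfu.R`; subcommands `simulate`, `segment`,
`featurize`, `crossval`, `report`), chaining the stages through plain
CSV/TSV/JSON files.

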