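# aaaquant

Abdominal aortic aneurysm (AAA) boundary detection and volume
quantification from per-slice aortic cross-section profiles.

## The problem

Segmentation pipelines for CT angiography reduce an aortic scan to a 1-D
signal: the number of segmented pixels on each axial slice, superior to
inferior — a surrogate for cross-sectional area. On that signal an aneurysm
is a sustained enlargement, and a segmentation model trained only on normal
anatomy that stops producing masks on pathological slices leaves a
tell-tale collapse toward zero. `aaaquant` is for researchers who have such
pixel-count profiles (plus slice-level start/end annotations for
evaluation) and want automated aneurysm screening, boundary placement and
surrogate volume measurement, with a full evaluation harness and a
synthetic signal generator so every component is testable without patient
data.

## What it computes

**Rule-based systems.** Both compare each slice count with a rolling
baseline: the mean of the `window` most recent slices judged normal (the
first `window` slices seed it; anomalous slices are excluded, so the
baseline holds at normal caliber through an anomaly). A slice is anomalous
when its count leaves the band `[lower, upper] x baseline`.

* `screen_failure(profile)` — binary triage: a run of at least
  `persistence` consecutive anomalous slices (defaults: window 4,
  140 % / 50 % thresholds, persistence 4) labels the scan aneurysmal.
* `detect_boundaries_expert(profile)` — boundary localization: the largest
  run of at least `window` anomalous slices (defaults: window 4,
  120 % / 80 %) is the aneurysm; its first/last slices are start/end.
  `grid_search(cohort)` tunes `(window, upper, lower)` for mean interval
  Dice.

**Learned detector.** `train_detector` / `predict_boundaries` /
`cross_validate` — a stacked bidirectional LSTM (RcppArmadillo core with
hand-verified backpropagation through time) labels each of 200 positions
with an aneurysm probability; training uses Adam (lr 0.0003, batch 10) on
`BCE + (1 − soft-Jaccard)` with early stopping; the longest above-threshold
run decodes to boundaries. Cross-validation is strictly patient-level.

**Metrics and quantities.** Interval Dice `2TP/(2TP+FP+FN)` on slice sets;
`R² = 1 − RSS/TSS`, MAE and MSE on boundary indices; surrogate volume
`V = Σ_{i=s..e} P_i` (unit-less pixel sum over the annotated interval);
enlargement above a linearly interpolated normal baseline; confusion-matrix
classification rates.

**Synthetic cohorts.** `generate_cohort` draws seeded profiles — baseline
caliber, multiplicative noise, distal taper, raised-cosine aneurysm bump
(closed-form ground-truth annotation), optional segmentation dropout — and
`render_mask_stack` turns any profile into binary disk masks that
round-trip exactly through `extract_profile`.

## Worked example

```r
library(aaaquant)

# 40 synthetic AAA patients: 200 slices, 3 % noise, seeded
coh <- generate_cohort(40, 1, synthetic_params(noise_sd_frac = 0.03), seed = 42)

run_evaluation(coh, pipeline_config(detector = "expert"))
#> <pipeline_result> detector: expert
#> <eval_report> [expert (fixed rule)]
#>   mean Dice 0.986 | R2 start 0.999 end 0.999 volume 0.998
#>   MAE start 0.450 end 0.650 | MSE start 0.700 end 1.100
#>   predicted 40, missed 0

prof <- coh$profiles[["SYN001"]]
detect_boundaries_expert(prof)
#> <boundary_annotation> patient SYN001: slices [96, 133]
coh$annotations[["SYN001"]]
#> <boundary_annotation> patient SYN001: slices [97, 133]
volume_surrogate(prof, detect_boundaries_expert(prof))
#> [1] 56398
```

The report reads: across 40 patients the rule's predicted intervals
overlap the true aneurysm extent with mean Dice 0.986, start and end
slices are off by under one slice on average (MAE 0.45 / 0.65), and the
predicted surrogate volumes explain 99.8 % of the variance in the true
ones. For SYN001 the detected interval [96, 133] misses the true start by
one slice; its surrogate volume is the pixel sum over those slices.

The dropout screen on a simulated segmentation failure:

```r
p <- generate_failure_profile(synthetic_params(dropout = TRUE, seed = 9), "F01")
screen_failure(p$profile)
#> <screen_result> F01: aneurysm, flagged slices [83, 117]

classification_metrics(tp = 15, fp = 2, fn = 2, tn = 14)
#> $accuracy 87.9  $precision 88.2  $recall 88.2  $specificity 87.5  $f1 88.2
```

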