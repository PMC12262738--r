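---
title: "Methods: aneurysm boundary detection and quantification from slice profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aneurysm boundary detection and quantification from slice profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaaquant)
```

## The signal

Modern aortic segmentation pipelines (a U-Net locating the aorta, a
promptable tracker propagating the mask down to the iliac bifurcation)
reduce a contrast-enhanced CT angiogram to a simple one-dimensional signal:
the number of segmented pixels on each axial slice, ordered superior to
inferior. Pixel count is a surrogate for aortic cross-sectional area, so an
abdominal aortic aneurysm (AAA) — a focal dilation of 3 cm diameter or more
against a roughly 2 cm normal aorta — appears as a sustained enlargement of
the count, and a segmentation model trained only on normal anatomy that
*stops* producing masks on pathological slices appears as a collapse of the
count toward zero. Everything in this package operates on that signal
(`slice_profile`), on inclusive 0-based start/end slice annotations
(`boundary_annotation`), or on the binary mask stacks the counts come from
(`mask_stack`).

Counts carry no physical calibration: the volume statistic
(`volume_surrogate`) is the plain sum of counts across the annotated
interval, a unit-less quantity proportional to true volume but deliberately
not expressed in mm³, since slice thickness and pixel spacing are not part
of the signal. `enlargement_surrogate` additionally subtracts a straight
"normal vessel" chord interpolated between the counts at the two
boundaries, clipping negative excess at zero so the statistic is
non-negative by construction.

## The two rule-based systems

Both rules compare each slice's count with a **rolling normal baseline**:
the mean of the `window` most recent slices judged normal so far. The first
`window` slices seed the baseline and are never flagged. A slice is
anomalous when its count exceeds `upper` x baseline (enlargement) or falls
below `lower` x baseline (dropout/collapse); anomalous slices are *excluded*
from the baseline, which therefore holds at normal-caliber level throughout
an anomaly and resumes rolling when counts return to normal.

The exclusion is the load-bearing design choice. A baseline that keeps
averaging the most recent four slices regardless of their state is dragged
upward along the rising limb of an aneurysm: for a smooth enlargement the
ratio of a slice to the mean of its four predecessors rarely exceeds ~1.15
even when the vessel has doubled in area, so a 120 % threshold would never
fire on exactly the morphology the rule exists to find. Tracking *normal*
slices instead means the threshold is applied against the vessel's actual
normal caliber, which is the clinically meaningful reference ("120 % of
normal" is a statement about anatomy, not about the previous four slices),
and it makes the flagged region commensurable with annotations defined as
"area above 1.2 x normal".

* `screen_failure` (defaults window 4, upper 1.4, lower 0.5, persistence 4)
  is a binary triage classifier: a profile is called aneurysmal when some
  run of at least `persistence` consecutive anomalous slices exists; the
  first and last flagged slices of qualifying runs are reported. It is
  intended for profiles from a normal-anatomy-only segmentation model,
  where pathology manifests as dropout.
* `detect_boundaries_expert` (defaults window 4, upper 1.2, lower 0.8)
  localizes boundaries: maximal anomalous runs of length at least `window`
  are candidate abnormality regions, and the region of greatest slice
  extent wins, ties going to the earliest. Its first and last slices are
  the aneurysm start and end. Both thresholds being ratios makes the
  detector exactly invariant to rescaling all counts by a positive
  constant.

`grid_search` tunes `(window, upper, lower)` by exhaustive evaluation,
maximizing mean interval Dice over an annotated cohort. Ties are broken
toward the smaller window, then the upper threshold closest to 1, then the
lower threshold closest to 1 — among equally good rules, prefer the least
aggressive one. The default grid (windows 2–8, uppers 1.05–1.50, lowers
0.50–0.95 in steps of 0.05) brackets the default thresholds of both rule
systems. When the pipeline runs a grid search it does so on the full cohort
it is then evaluated on; the report labels this as in-sample, because no
held-out protocol is defined for the rule systems.

## The LSTM slice labeler

The learnable detector treats boundary placement as per-slice binary
sequence labeling. Profiles are max-scaled (each divided by its own maximum
count — scale-free like the rules, preserving the relative 120 %/80 %
geometry; an all-zero profile maps to zeros with scale 1) and zero-padded
distally to 200 positions; longer profiles are truncated distally with a
warning. The network is a stack of bidirectional LSTM layers (default two,
600 hidden units per direction — the full-scale configuration) whose
concatenated per-timestep states feed a small shared fully connected stack
(default widths 256 and 64, ReLU) ending in one sigmoid unit per timestep,
i.e. 200 per-slice probabilities. A per-timestep head was chosen over
flattening the sequence into one dense layer: it is the direct reading of
"slice-wise classification scores", has far fewer parameters, and is
translation-consistent along the slice axis.

Training (`train_detector`) minimizes
`BCE + jaccard_weight * (1 - soft-Jaccard)` with Adam (learning rate
0.0003, batch size 10). The soft Jaccard on probabilities,
`sum(p*y) / sum(p + y - p*y)` per profile, counteracts the class imbalance
of narrow aneurysm intervals; its weight defaults to 1. Binary
cross-entropy is implemented as the standard *negative* mean log-likelihood
(a non-negative loss that is minimized). Early stopping watches validation
loss with a default patience of 100 epochs against a 1000-epoch ceiling,
and the weights at the best validation loss are restored. One seed controls
weight initialization, batch order and fold assignment; identical seeds and
data reproduce the loss history bitwise under deterministic BLAS. Train and
validation cohorts sharing a patient is an error, not a warning.

The recurrent core (forward pass, backpropagation through time, and the
loss gradients) is implemented in C++ via RcppArmadillo and verified
against finite-difference gradients in the test suite. Decoding is
deterministic: positions at or above the fixed threshold (default 0.5, the
natural operating point of a sigmoid head; configurable) form runs, the
longest run wins (ties toward the earliest — the same largest-region
principle as the expert rule), and padding positions are excluded before
mapping back to slice indices.

`cross_validate` partitions patients once into k seeded folds (default 5,
i.e. 80/20 splits) with strict patient-level separation, carves 15 % of
each fold's training patients off for early stopping, and averages fold
reports into a pooled report.

## Evaluation metrics

`interval_dice` is the Dice coefficient on slice-index intervals treated as
slice sets, `2TP / (2TP + FP + FN)`; two absent annotations score 1, one
absent scores 0. `r_squared` is the direct `1 - RSS/TSS` formula on paired
values (predicted vs true start slices, end slices, or surrogate volumes),
not a fitted regression's R²; it errors on constant truth (TSS = 0) and can
be negative. `mae_mse` are plain means of absolute and squared index
errors. `classification_metrics` turns a confusion matrix into accuracy,
precision, recall, specificity and F1 as percentages at one decimal,
returning `NULL` where a denominator is zero. `evaluate_cohort` assembles
the cohort report: Dice is averaged over every annotated patient with
missed detections contributing 0, while the boundary regressions and the
volume R² use only patients where both truth and prediction mark an
aneurysm — a missed case is visible in `n_missed` rather than silently
distorting a regression.

## The synthetic generator

Because the underlying patient cohort is private, the package ships a
seeded generator (`generate_profile`, `generate_cohort`) that emulates the
signal's structure: a constant normal caliber (default 300 pixels) with
multiplicative Gaussian noise (default sd 3 % of the local mean — area
noise scales with area), an optional linear distal taper (default 10 % over
the profile), and a raised-cosine aneurysm bump. The raised cosine was
chosen over a Gaussian so the annotated region has a closed form: the bump
multiplier `1 + A * 0.5 * (1 + cos(pi * (i - c)/h))` exceeds the annotation
threshold (default 1.2, matching the expert rule's start criterion) on an
analytically known slice interval, which the tests exploit. Dropout
profiles (`generate_failure_profile`) replace counts inside the annotated
interval with uniform draws in `[0, 0.05 * baseline]`, emulating a
segmentation model that fails on pathology.

Cohort-level randomization draws the bump amplitude uniformly from 3–8 and
the half-width from 15–30 slices. Those ranges are anatomical choices: a
surgical AAA cohort presents aneurysms of roughly 4–6 cm diameter against a
2 cm aorta, and since area scales with diameter squared the peak excess is
4–9 times baseline area, i.e. an amplitude of 3–8; at ~2 mm effective slice
spacing, aneurysm lengths of 5–12 cm correspond to half-widths of 15–30
slices over a 200-slice thoracic-to-iliac segment. `render_mask_stack`
inverts profile extraction, building per-slice centered disks with exactly
the profile's pixel count (lattice points taken in distance order, ties
broken on coordinates), so `extract_profile` of a rendered stack is the
identity.

What the generator does *not* emulate: tracker-induced mask irregularities
and drift, plateau- or saccular-shaped aneurysms (the bump is symmetric and
unimodal), partial dropout, inter-observer annotation variability, and
branch-vessel artifacts. Tests passing on synthetic cohorts therefore
demonstrate correctness of the algorithms under the stated signal model,
not clinical performance on real CTA-derived profiles.

## Numerical choices and degenerate inputs

* `contrast_stretch` maps the observed input range affinely onto
  `[10, 245]` (the output range of 8-bit normalization), rounding half away
  from zero so results are bit-exact across platforms; a constant image
  maps to `out_low`. Reading the 10–245 figure as an output range rather
  than input percentile clipping follows from its role in 8-bit grayscale
  conversion.
* Probabilities are clipped to `[1e-7, 1 - 1e-7]` inside the BCE.
* LSTM weights initialize uniformly in `[-1/sqrt(h), 1/sqrt(h)]` with
  forget-gate biases at +1 so early training retains memory.
* A profile shorter than the rule window plus its persistence requirement
  is an error; an absent annotation passed to a volume statistic is an
  error; `enlargement_surrogate` of a single-slice interval is 0 by
  convention.
* All boundary indices are 0-based and inclusive at both ends, matching
  the interval sum of the volume surrogate and the CSV interchange format.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script exercise the full stack at
simulation scale chosen by the package: rule checks use 50-profile
noiseless cohorts, and the LSTM study trains a 2-layer bidirectional
network with 32 hidden units per direction and fully connected widths
(32, 16) on a 200-profile cohort (140 train / 30 validation / 30 held-out)
for up to 120 epochs with early-stopping patience 30. On this generator a
unit-amplitude bump is already learned to held-out mean interval Dice
around 0.99, so the compact network is the appropriate size for the
simulated signal; the 600-unit full-scale configuration remains the default
of `detector_spec()` for real cohorts.

## Known limitations

The expert rule reports only the single largest abnormality region, so
multi-aneurysm profiles yield one interval. The screen's first/last flagged
slices span all qualifying runs, which overestimates extent when separate
anomalies coexist. Grid search inside the pipeline is in-sample by design
and flagged as such. Surrogate volumes are uncalibrated pixel sums and not
comparable across scanners or reconstruction settings. The LSTM operates on
a fixed 200-position canvas; profiles longer than 200 slices are truncated
distally.
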