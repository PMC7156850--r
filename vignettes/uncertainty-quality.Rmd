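---
title: "Judging voxel-wise uncertainty in tumor segmentation: calibration, error localization, and failure detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Judging voxel-wise uncertainty in tumor segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5,
                      fig.height = 4)
library(uqseg)
library(dplyr)
```

## The problem

Modern segmentation networks for brain-tumor MRI attach a voxel-wise
uncertainty estimate to their output — a sigmoid probability, the entropy
of Monte-Carlo dropout or ensemble averages, a predicted variance, or the
output of an auxiliary error-prediction network. Before such maps are used
clinically (for visual feedback, guided correction, or flagging cases for
review), two distinct questions must be answered:

1. **Is the uncertainty well calibrated?** When the model reports 70%
   confidence, is it right 70% of the time — and is that true for *each
   patient*, not just on average over a data set?
2. **Is the uncertainty useful?** Does it sit where the segmentation is
   actually wrong, and can it be aggregated into a per-subject score that
   flags failed segmentations?

`uqseg` implements the full evaluation pipeline for these questions on
hierarchical tumor regions (whole tumor WT ⊇ tumor core TC ⊇ enhancing
tumor ET), together with a seeded synthetic cohort generator so that every
stage can be exercised and tested without clinical data.

## Uncertainty and confidence maps

All probability-output methods are reduced to one voxel-wise uncertainty
via the normalized binary entropy

$$H(p) = -\left[p \log p + (1-p)\log(1-p)\right] / \log 2 \in [0, 1],$$

with the convention $0 \log 0 = 0$ ( `normalized_entropy()`; internally
$p$ is clamped to $[10^{-12}, 1-10^{-12}]$ before the logarithm, and the
endpoint values are set exactly to zero). Sample stacks from dropout or
ensembles are first averaged voxel-wise (`combine_samples()`); the entropy
of the mean — not the variance of the samples — is the uncertainty.
Uncertainty-native maps (predicted variances, error probabilities) are
min–max normalized to $[0,1]$ with *cohort-global* extrema
(`normalize_native_map()`): per-subject normalization would destroy
comparability across subjects and is rejected.

For calibration analysis every method must live on a common
foreground-probability axis. Probability outputs are used directly;
uncertainty-native maps are translated by

$$c = y\,(1 - 0.5\,q) + (1 - y)\,0.5\,q,$$

which maps predicted-foreground voxels into $[0.5, 1]$ and background
voxels into $[0, 0.5]$ (`uncertainty_to_confidence()`).

## Calibration: dataset level versus subject level

`reliability_diagram()` bins confidences into $M$ equal-width bins
(default $M = 10$; the bin statistic is the *mean confidence in the bin*,
not the midpoint) and records the empirical foreground fraction per bin.
All voxel-level calibration is restricted to the brain mask — otherwise
the huge, confidently-correct extra-cranial background dominates every
statistic. Two scalars summarize a diagram:

* `expected_calibration_error()` — count-weighted mean absolute gap,
  $\mathrm{ECE} = \sum_m \frac{n_m}{N}\,|c_m - a_m|$;
* `average_calibration_error()` — unweighted mean over occupied bins,
  which exposes sparse badly-calibrated bins the ECE hides.

The package always distinguishes *dataset scope* (all subjects' voxels
pooled, `dataset_reliability()`) from *subject scope*
(`cohort_calibration()`, which reports the unweighted mean subject ECE).
The distinction matters because miscalibrations of opposite sign cancel
when pooled: a cohort of half over-confident, half under-confident
subjects can look almost perfectly calibrated at dataset level. The
synthetic cancellation experiment below makes that concrete.

### Classifying subjects

`classify_subject_calibration()` labels a subject as over-confident,
under-confident or well calibrated from the *signed* calibration error,
folded about 0.5: bins with $c_m \ge 0.5$ contribute $c_m - a_m$, bins
below contribute $a_m - c_m$. Folding is essential — on the raw
foreground-probability axis a temperature distortion pushes high bins up
and low bins down symmetrically, and the unfolded signed sum cancels to
zero, classifying badly miscalibrated subjects as fine. Folded, the sum is
the signed error on the confidence-of-predicted-class axis, which moves in
the intuitive direction: sharpening (temperature $\tau < 1$) makes it
positive, smoothing ($\tau > 1$) negative.

The dead-band (default tolerance 0.002) was chosen between two scales
measured on the package's calibration study conditions: the sampling noise
of a perfectly calibrated subject at $5\times10^5$ brain voxels is around
$3\times10^{-4}$, while boundary-limited temperature miscalibration
produces signed errors of $4\times10^{-3}$ and up. Any tolerance between
those classifies both reliably; a dead-band as large as 0.01 would absorb
genuine miscalibration because the signed error is diluted by the large
confidently-correct brain bulk.

## Does uncertainty localize errors?

The error map is the union of false positives and false negatives,
`pred XOR gt`. The uncertainty–error overlap
(`uncertainty_error_overlap()`) is the Dice coefficient between the
thresholded uncertainty $U = \{q \ge t\}$ and the error set $E$ — by
construction insensitive to the confidently-correct background, unlike the
ECE. The threshold is swept over $\{0.05, 0.10, \ldots, 0.95\}$ on the
validation split and the argmax frozen (`select_threshold()`; ties go to
the lower threshold, and $U$ uses a closed inequality so the top grid
value is attainable). The frozen threshold is reused on test subjects and
by the automatic feature extraction. A threshold-free companion,
`uncertainty_error_auc_pr()`, ranks voxels by uncertainty and computes the
step-interpolated precision–recall AUC for "this voxel is an error"; a
score independent of the errors yields roughly the error prevalence.

## Subject-level aggregation and failure detection

Three aggregation families reduce a voxel map to per-subject predictors of
segmentation quality:

* **mean** — the negative mean uncertainty over the brain mask
  (`mean_aggregate()`), oriented so larger means predicted-better.
* **prior knowledge** (`prior_knowledge_features()`) — nine features:
  three boundary-deemphasizing weightings (zeroing the three-voxel
  `boundary_band()`; multiplying by the Euclidean distance in mm to the
  predicted boundary, which vanishes on the boundary and up-weights remote
  uncertainty; dividing by the predicted volume) crossed with three
  reducers (mean over the brain mask, sum, and
  $\mathrm{logsum} = \log(1 + \text{sum})$ — the $1+$ keeps the reducer
  finite on empty support).
* **automatic** (`automatic_features()`) — shape, first-order and
  gray-level run-length descriptors of the *thresholded* map
  $\{q \ge t^\*\}$: volume, mesh surface area, sphericity
  $\pi^{1/3}(6V)^{2/3}/A$, surface-to-volume ratio; mean, variance,
  histogram entropy, percentiles, energy of $q$ inside the region; and
  run-length features (RLN, GLN, SRE, LRE, run percentage) of the map
  discretized at a fixed bin width of 0.05 and scanned along the three
  grid axes. Pinning the discretization and directions keeps the panel
  deterministic; the panel is configurable but these named features are
  always present.

The prior-knowledge and automatic families feed a random-forest regressor
of the true Dice coefficient (`fit_dice_regressor()`, 500 trees, recorded
seed; missing features from empty segmentations are imputed with 0 plus a
missingness indicator). Failure detection then binarizes quality at a
region-specific Dice cutoff — the package ships the multi-rater benchmark
values `interrater_dice_cutoffs()` (WT 0.85, TC 0.75, ET 0.74) but never
applies a hidden default — and scores the regressor output with Spearman's
$\rho$, the AUC-ROC with *failure as the positive class* (lower predicted
quality = more likely failed; the AUC equals the probability that a failed
subject scores below a successful one), and the accuracy at the maximal
Youden index $J = \text{sens} - (1 - \text{spec})$, computed on the same
cohort and therefore an apparent accuracy. Feature importances are
compared across models by accumulating ranks
(`rank_accumulate_importance()`).

## The synthetic cohort generator

`cohort_spec()` + `generate_cohort()` produce seeded cohorts of tumor-like
phantoms: an ellipsoidal brain, nested WT/TC/ET regions built from one
deformed ellipsoid (one shared low-frequency radial deformation guarantees
the hierarchy), and a probabilistic "predictor" whose latent field is the
Gaussian-blurred ground truth. Cohorts are lazy: a subject is a pure
function of (spec, master seed, index) and is regenerated on demand, so a
100-subject cohort never holds 100 sets of volumes in memory.

Two generator modes trade realism against exactness:

* **calibration mode** redraws the ground truth voxel-wise as
  Bernoulli$(p^\*)$ of the latent field (one shared uniform per voxel
  keeps the redrawn regions nested), so the latent field is *perfectly
  calibrated by construction*; the reported probability is
  $\mathrm{sigmoid}(\mathrm{logit}(p^\*)/\tau)$ with per-subject
  temperature $\tau$. The redrawn labels are speckled and anatomically
  implausible, which is why this mode exists separately.
* **morphology mode** keeps the clean deterministic labels and instead
  jitters the decision boundary with a smooth logit-space noise field —
  the right setting for shape-feature and aggregation experiments.

Predictions threshold the reported probability at 0.5 and are therefore
invariant to $\tau$.

Failure modes are injected per subject: `remote_blob` adds confident
false-positive spheres far from the tumor (Dice drops while the mean
uncertainty barely moves) together with remote *uncertainty-only* patches
(probability peak 0.45, i.e. entropy near 1 without any prediction
change) — the diffuse far-from-boundary uncertainty that failed
segmentations exhibit and that distance-weighted aggregation keys on;
`missed_core` suppresses the probability in half of the tumor core;
`boundary_jitter` adds extra boundary noise (amplitude 0 is exactly a
no-op).

### Study conditions

Two canonical settings are frozen as exported helpers and used by the
package's own tests and the acceptance script:

* `calibration_study_spec()` — calibration mode, 128×128×80 grid at 1 mm
  (≈ 5.7×10⁵ brain voxels per subject), tumors of 16–20 mm radius with
  3 mm boundary blur so the transition zone is large enough to carry a
  measurable calibration signal.
* `failure_study_spec()` — morphology mode, 96×96×72 grid, 100 subjects
  split 35/9/56 into train/validation/test, 30% `remote_blob` subjects.
  Clean subjects vary in head size (±15%), boundary blur (1.5–2.5 mm),
  logit noise (amplitude 0.25–0.6) and temperature (0.7–1.5), so the mean
  uncertainty fluctuates across subjects for reasons unrelated to the
  blob failures — this inter-subject variability is what makes mean
  aggregation uninformative about blob-driven failures while the
  distance-weighted and shape features remain sensitive.

What passing tests on these cohorts do and do not show: the generator
emulates geometry, boundary-localized uncertainty, controllable
calibration and failure phenomenology, but not MR intensities, raters'
label noise, multifocal disease, or the uncertainty structure of any
particular network family. Results on synthetic cohorts validate the
*implementation and the qualitative mechanisms*, not clinical performance.

## Numerical choices

* **Surface area.** Mesh area is computed by marching tetrahedra with
  linear interpolation on a Gaussian-smoothed indicator (σ = 0.8 voxel).
  Meshing the raw binary mask systematically over-estimates the area of
  smooth shapes (a digital r = 12 ball comes out ~8% high even with a
  proper marching-cubes table), which biases sphericity down to ~0.92;
  light smoothing removes the voxelization staircase (ball sphericity
  0.996) while leaving flat axis-aligned faces exact. The residual cost is
  edge rounding on sharp polyhedra, which decays as σ/side; regions
  thinner than the smoothing support fall back to meshing the raw
  indicator. Distances use an exact separable Euclidean distance
  transform; both are implemented in compiled code.
* **Binning.** Right-closed equal-width bins; bin 1 includes 0. Empty bins
  are flagged `NA` and contribute nothing to the ECE; the ACE errors out
  when no bin is occupied.
* **Ties.** Threshold-sweep ties resolve to the lower threshold; Youden
  ties to the higher specificity; importance-rank ties alphabetically.
* **Degenerate inputs.** Both-empty Dice and U-E are 1, one-empty 0;
  empty predictions yield missing distance/volume features (imputed with
  indicators); an empty thresholded region yields an all-missing flagged
  feature row; constant native-map cohorts normalize to all-zeros.
* **Determinism.** Every stochastic step draws from a seed derived from
  the master seed and the subject index; fits record their seeds. Two
  pipeline runs from one config produce byte-identical tables.

## A worked example

A small end-to-end run on a synthetic cohort (kept small here; the
package's acceptance experiments use the full study conditions):

```{r example, eval = FALSE}
spec <- failure_study_spec(n_subjects = 40, seed = 1)
cohort <- generate_cohort(spec, compute_dice = FALSE)

# voxel level: calibration and error localization
cal <- cohort_calibration(cohort, regions = "WT")
cal$mean_subject_ece
sel <- select_threshold(cohort, "WT")
sel

# subject level: features, regressor, failure detection
feats <- cohort_features(cohort, regions = "WT",
                         thresholds = list(WT = sel))
train <- feats |> filter(family == "prior_knowledge", split == "train")
test  <- feats |> filter(family == "prior_knowledge", split == "test")
fit <- fit_dice_regressor(train, seed = 7)
res <- evaluate_failure_detection(predict(fit, test), test$true_dice,
                                  interrater_dice_cutoffs()[["WT"]],
                                  region = "WT", family = "prior_knowledge")
glance(res)
autoplot(res)
```

## Known limitations

* The subject-calibration decision rule (folded signed error with a fixed
  dead-band) is a documented convention; no community standard exists.
* The automatic feature panel is a deterministic ~25-feature subset of the
  much larger panels radiomics toolkits extract; it contains the features
  that matter for this analysis (sphericity, run-length non-uniformity,
  first-order statistics) but is not a reimplementation of any specific
  toolkit's 102-feature list.
* Youden accuracy is apparent (computed on the ROC cohort), and no
  confidence intervals are attached to AUCs.
* Predictions with broken region hierarchy (possible with independent
  sigmoid heads) are evaluated per region as-is and never repaired.
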