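# Canonical study conditions. These fix the synthetic-cohort parameters
# used by the package's own experiments (tests, acceptance runs, vignette)
# so that every analysis names one reproducible setting.

#' Study conditions for calibration experiments
#'
#' Calibration-mode cohort on a grid whose brain mask holds at least half a
#' million voxels, so subject-level reliability bins are densely occupied.
#' The ground truth is redrawn voxel-wise from the latent field, making the
#' latent probabilities perfectly calibrated by construction; the reported
#' probabilities are temperature-distorted by `tau`.
#'
#' @param n_subjects number of subjects.
#' @param seed master seed.
#' @param tau temperature (scalar, vector or function; see [cohort_spec()]).
#' @param ... overrides passed on to [cohort_spec()].
#' @return a `uq_cohort_spec`.
#' @export
calibration_study_spec <- function(n_subjects = 10, seed = 1L, tau = 1, ...) {
  args <- list(n_subjects = n_subjects, seed = seed, tau = tau,
               mode = "calibration",
               dims = c(128, 128, 80),
               brain_scale_range = c(1, 1),
               boundary_sigma_mm = 3,
               wt_radius_range = c(16, 20),
               deform_amplitude = 0.1,
               center_frac = 0.1,
               failure_mix = c(clean = 1))
  do.call(cohort_spec, utils::modifyList(args, list(...)))
}

#' Study conditions for the failure-detection experiment
#'
#' Morphology-mode cohort in which 30% of subjects are corrupted by remote
#' high-confidence false-positive blobs accompanied by remote
#' uncertainty-only patches. Per-subject boundary blur, logit noise,
#' temperature and head size all vary, so clean subjects span a realistic
#' range of difficulty; the blobs decouple mean uncertainty from
#' segmentation quality while leaving a distance-weighted and shape
#' signature that the richer aggregation families can exploit.
#'
#' @param n_subjects number of subjects (default 100, split 35/9/56 into
#'   train/validation/test).
#' @param seed master seed.
#' @param ... overrides passed on to [cohort_spec()].
#' @return a `uq_cohort_spec`.
#' @export
failure_study_spec <- function(n_subjects = 100, seed = 1L, ...) {
  args <- list(n_subjects = n_subjects, seed = seed,
               dims = c(96, 96, 72),
               brain_scale_range = c(0.85, 1.1),
               tau = function(n) runif(n, 0.7, 1.5),
               failure_mix = c(clean = 0.7, remote_blob = 0.3),
               blob_unc_radius_mm = 4)
  do.call(cohort_spec, utils::modifyList(args, list(...)))
}

#' Dice cutoffs from the multi-rater brain-tumor segmentation literature
#'
#' Mean inter-rater Dice overlaps reported for the 2013 multi-rater
#' brain-tumor benchmark: 0.85 (whole tumor), 0.75 (tumor core) and 0.74
#' (enhancing tumor). An automated segmentation below these levels
#' disagrees with the reference more than a second human rater would, which
#' is the package's working definition of a failed segmentation. Supplied
#' as a convenience; [binarize_quality()] itself has no default.
#'
#' @return named numeric vector over WT, TC, ET.
#' @export
interrater_dice_cutoffs <- function() {
  c(WT = 0.85, TC = 0.75, ET = 0.74)
}
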