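# Does the uncertainty sit where the segmentation is wrong?
# Error maps, uncertainty-error overlap, validation threshold sweep, AUC-PR.

#' Segmentation error map
#'
#' Union of false positives and false negatives: `pred XOR gt`.
#'
#' @param pred,gt binary volumes of one shape.
#' @return logical volume (TRUE = misclassified voxel).
#' @export
error_map <- function(pred, gt) {
  assert_binary(pred); assert_binary(gt)
  assert_same_shape(pred, gt, "pred", "gt")
  xor(as_mask(pred), as_mask(gt))
}

#' Uncertainty-error overlap (U-E)
#'
#' Dice overlap between the thresholded-uncertainty region
#' `U = {q >= threshold}` and the error region `E`:
#' `U-E = 2 |U ∩ E| / (|U| + |E|)`. Voxels outside `U ∪ E` (the
#' confidently-correct background) do not influence the score, unlike the
#' ECE. Conventions: 1 when both sets are empty (a perfect segmentation
#' with no thresholded uncertainty is perfect localization), 0 when exactly
#' one is empty.
#'
#' @param q an `uq_uncertainty` or bare \[0, 1\] volume.
#' @param E logical error volume (from [error_map()]).
#' @param threshold scalar in (0, 1); the set U uses `q >= threshold`
#'   (closed, so a grid threshold of 0.95 is attainable at q = 0.95).
#' @param mask optional evaluation mask.
#' @return scalar in \[0, 1\].
#' @export
uncertainty_error_overlap <- function(q, E, threshold, mask = NULL) {
  qv <- if (inherits(q, "uq_uncertainty")) q$values else q
  stopifnot(threshold > 0, threshold < 1)
  assert_same_shape(qv, E, "q", "E")
  U <- qv >= threshold
  E <- as_mask(E)
  if (!is.null(mask)) {
    mask <- as_mask(mask)
    U <- U & mask; E <- E & mask
  }
  nu <- sum(U); ne <- sum(E)
  if (nu == 0 && ne == 0) return(1)
  if (nu == 0 || ne == 0) return(0)
  2 * sum(U & E) / (nu + ne)
}

#' The standard threshold sweep grid
#'
#' Thresholds 0.05 to 0.95 in steps of 0.05 (19 values).
#'
#' @return numeric vector.
#' @export
ue_threshold_grid <- function() round(seq(0.05, 0.95, by = 0.05), 10)

# Fast per-subject U-E over the whole grid: histogram the uncertainty once.
ue_sweep_subject <- function(qv, E, mask = NULL, grid = ue_threshold_grid()) {
  if (!is.null(mask)) {
    mask <- as_mask(mask)
    qv <- qv[mask]; E <- as_mask(E)[mask]
  } else {
    qv <- as.vector(qv); E <- as.vector(as_mask(E))
  }
  ne <- sum(E)
  # |U(t)| and |U(t) ∩ E| for all grid thresholds via cumulative counts
  bin <- findInterval(qv, grid)  # 0 => below all thresholds; k => >= grid[k]
  tot <- tabulate(bin + 1L, nbins = length(grid) + 1L)
  err <- tabulate(bin[E] + 1L, nbins = length(grid) + 1L)
  nU <- rev(cumsum(rev(tot)))[-1L]     # counts with q >= grid[k]
  nUE <- rev(cumsum(rev(err)))[-1L]
  ue <- ifelse(nU == 0 & ne == 0, 1,
               ifelse(nU == 0 | ne == 0, 0, 2 * nUE / (nU + ne)))
  names(ue) <- sprintf("%.2f", grid)
  ue
}

#' Select the U-E threshold on the validation split
#'
#' Sweeps the 19-point threshold grid, scores each threshold by the mean
#' subject U-E over the validation subjects of the cohort, and returns the
#' argmax (ties broken toward the lower threshold). The selected threshold
#' is meant to be frozen and reused on test subjects and by the automatic
#' feature extraction.
#'
#' @param cohort a `uq_cohort`.
#' @param region region name.
#' @param method_id identifier of the uncertainty method (bookkeeping).
#' @param grid threshold grid; default [ue_threshold_grid()].
#' @param split split used for the sweep; default `"validation"`.
#' @return object of class `uq_threshold`: list with `method_id`, `region`,
#'   `threshold` and `sweep` (tibble threshold / mean_ue / n_subjects).
#' @export
select_threshold <- function(cohort, region, method_id = "entropy",
                             grid = ue_threshold_grid(),
                             split = "validation") {
  idx <- which(cohort$manifest$split %in% split)
  if (length(idx) == 0) stop("empty validation split", call. = FALSE)
  acc <- matrix(NA_real_, nrow = length(idx), ncol = length(grid))
  for (k in seq_along(idx)) {
    s <- cohort_subject(cohort, idx[k])
    q <- subject_uncertainty(s, region)
    E <- error_map(s$pred_labels[[region]], s$gt_labels[[region]])
    acc[k, ] <- ue_sweep_subject(q$values, E, s$brain_mask, grid)
  }
  scores <- colMeans(acc)
  best <- which.max(scores)  # which.max takes the first (lowest) on ties
  structure(list(method_id = method_id, region = region,
                 threshold = grid[best],
                 sweep = tibble::tibble(threshold = grid, mean_ue = scores,
                                        n_subjects = length(idx))),
            class = "uq_threshold")
}

#' @export
print.uq_threshold <- function(x, ...) {
  cat(sprintf("<uq_threshold> %s / %s: threshold %.2f (mean validation U-E %.3f over %d subjects)\n",
              x$method_id, x$region, x$threshold,
              max(x$sweep$mean_ue), x$sweep$n_subjects[1]))
  invisible(x)
}

#' Precision-recall AUC of uncertainty as an error score
#'
#' Threshold-free counterpart of the U-E overlap: ranks voxels by
#' uncertainty and computes the area under the precision-recall curve for
#' the task "this voxel is a segmentation error", inside the evaluation
#' mask. Step-interpolated (average-precision) form; ties are grouped. A
#' score independent of the errors gives roughly the error prevalence.
#'
#' @param q an `uq_uncertainty` or bare volume.
#' @param E logical error volume.
#' @param mask optional evaluation mask.
#' @return scalar in \[0, 1\], or `NA` (with a warning) if `E` has no
#'   positive voxel inside the mask.
#' @export
uncertainty_error_auc_pr <- function(q, E, mask = NULL) {
  qv <- if (inherits(q, "uq_uncertainty")) q$values else q
  assert_same_shape(qv, E, "q", "E")
  E <- as_mask(E)
  if (!is.null(mask)) {
    mask <- as_mask(mask)
    qv <- qv[mask]; E <- E[mask]
  }
  y <- as.integer(E)
  P <- sum(y)
  if (P == 0) {
    warning("error map empty inside mask; AUC-PR undefined")
    return(NA_real_)
  }
  auc_pr(as.numeric(qv), y)
}

# average-precision AUC-PR with tie grouping; scores high = positive
auc_pr <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # group ties
  grp <- cumsum(!duplicated(s))
  tp_g <- rowsum(y, grp, reorder = FALSE)[, 1]
  n_g <- tabulate(grp)
  tp <- cumsum(tp_g); n <- cumsum(n_g)
  P <- sum(y)
  prec <- tp / n
  rec <- tp / P
  drec <- diff(c(0, rec))
  sum(prec * drec)
}
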