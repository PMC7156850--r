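# Scoring aggregated uncertainty against true segmentation quality:
# Dice, success/failure binarization, Spearman rho, ROC/AUC, Youden accuracy.

#' Dice coefficient of two binary volumes
#'
#' `2 |P ∩ G| / (|P| + |G|)`; 1 when both are empty, 0 when exactly one is.
#'
#' @param pred,gt binary volumes of one shape.
#' @return scalar in \[0, 1\].
#' @export
dice_coefficient <- function(pred, gt) {
  assert_same_shape(pred, gt, "pred", "gt")
  p <- as_mask(pred); g <- as_mask(gt)
  np <- sum(p); ng <- sum(g)
  if (np == 0 && ng == 0) return(1)
  if (np == 0 || ng == 0) return(0)
  2 * sum(p & g) / (np + ng)
}

#' Binarize segmentation quality into success/failure
#'
#' A segmentation fails when its Dice falls below the cutoff — typically
#' the mean inter-rater Dice for the region, the level at which an
#' automated result is no better than a second human rater. Failure is the
#' positive class throughout the package. A Dice exactly at the cutoff
#' counts as successful (boundary convention).
#'
#' @param dice_values numeric vector of Dice coefficients.
#' @param cutoff scalar in (0, 1). Deliberately no default: cutoffs are
#'   region-specific and must come from configuration.
#' @return logical vector, TRUE = failed.
#' @export
binarize_quality <- function(dice_values, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0 || cutoff >= 1)
    stop("cutoff must be a scalar in (0, 1)", call. = FALSE)
  dice_values < cutoff
}

#' Spearman rank correlation
#'
#' Rank correlation (average ranks on ties) between predicted and actual
#' values; chosen over Pearson because aggregation scores need not relate
#' linearly to Dice.
#'
#' @param predicted,actual numeric vectors (>= 3 pairs).
#' @return rho in \[-1, 1\], or NA (with a warning) for constant input.
#' @export
spearman_correlation <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  if (length(predicted) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (sd(predicted) == 0 || sd(actual) == 0) {
    warning("constant input; Spearman rho undefined")
    return(NA_real_)
  }
  cor(predicted, actual, method = "spearman")
}

#' ROC curve and AUC for failure detection
#'
#' Scores are oriented as predicted quality: lower score = more likely
#' failure. The AUC equals the probability that a failed subject scores
#' below a successful one (ties counted half), so 1 is a perfect
#' separator, 0.5 random, and values below 0.5 indicate a direct rather
#' than inverse relation between score and failure.
#'
#' @param scores numeric vector (higher = predicted better).
#' @param failure_labels logical vector (TRUE = failed).
#' @return list with `roc` (tibble: threshold, fpr, tpr), `auc`; or NULL
#'   fields (with a warning) when only one class is present.
#' @export
roc_auc <- function(scores, failure_labels) {
  stopifnot(length(scores) == length(failure_labels))
  failure_labels <- as.logical(failure_labels)
  if (length(unique(failure_labels)) < 2) {
    warning("single-class cohort; ROC/AUC undefined")
    return(list(roc = NULL, auc = NA_real_))
  }
  # cases = failures (low scores); controls = successes (high scores)
  r <- pROC::roc(response = failure_labels, predictor = scores,
                 levels = c(FALSE, TRUE), direction = ">", quiet = TRUE)
  roc_tab <- tibble::tibble(threshold = r$thresholds,
                            fpr = 1 - r$specificities,
                            tpr = r$sensitivities)
  list(roc = roc_tab, auc = as.numeric(pROC::auc(r)))
}

#' Youden-index operating point and its accuracy
#'
#' Maximizes `J = sensitivity - (1 - specificity)` over the ROC points and
#' reports the classification accuracy at that threshold on the same
#' cohort (apparent accuracy). Ties in J are broken toward higher
#' specificity (fewer false alarms).
#'
#' @param roc tibble from [roc_auc()] (`threshold`, `fpr`, `tpr`).
#' @param scores,failure_labels the cohort the ROC was built on.
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden_j`,
#'   `accuracy`.
#' @export
youden_accuracy <- function(roc, scores, failure_labels) {
  stopifnot(is.data.frame(roc))
  failure_labels <- as.logical(failure_labels)
  j <- roc$tpr - roc$fpr
  spec <- 1 - roc$fpr
  best <- order(-j, -spec)[1]
  thr <- roc$threshold[best]
  # predicted failure: score below (or at) the threshold; pROC thresholds
  # are midpoints, so use < for the infinite end points safely
  pred_fail <- scores < thr
  acc <- mean(pred_fail == failure_labels)
  list(threshold = thr, sensitivity = roc$tpr[best],
       specificity = spec[best], youden_j = j[best], accuracy = acc)
}

#' Evaluate failure detection for one set of subject scores
#'
#' Bundles the subject-level evaluation: Spearman correlation between
#' scores and true Dice, success/failure binarization at the region's
#' Dice cutoff, ROC/AUC with failure as the positive class, and the
#' Youden-point accuracy.
#'
#' @param scores numeric vector of predicted-quality scores (higher =
#'   predicted better; e.g. negative mean uncertainty or predicted Dice).
#' @param true_dice numeric vector of true Dice coefficients.
#' @param cutoff region-specific Dice cutoff in (0, 1) (config-supplied).
#' @param region,family labels carried into the result.
#' @return object of class `uq_failure_result`.
#' @export
evaluate_failure_detection <- function(scores, true_dice, cutoff,
                                       region = NA_character_,
                                       family = NA_character_) {
  stopifnot(length(scores) == length(true_dice))
  if (length(scores) < 2) stop("need at least 2 subjects", call. = FALSE)
  labels <- binarize_quality(true_dice, cutoff)
  rho <- tryCatch(spearman_correlation(scores, true_dice),
                  warning = function(w) NA_real_,
                  error = function(e) NA_real_)
  ra <- withCallingHandlers(
    roc_auc(scores, labels),
    warning = function(w) invokeRestart("muffleWarning"))
  yj <- if (!is.null(ra$roc)) youden_accuracy(ra$roc, scores, labels) else
    list(threshold = NA_real_, sensitivity = NA_real_,
         specificity = NA_real_, youden_j = NA_real_, accuracy = NA_real_)
  structure(list(region = region, family = family,
                 pairs = tibble::tibble(predicted_score = scores,
                                        true_dice = true_dice,
                                        failure_label = labels),
                 spearman_rho = rho, roc = ra$roc, auc_roc = ra$auc,
                 youden_threshold = yj$threshold,
                 youden_accuracy = yj$accuracy,
                 youden_j = yj$youden_j,
                 dice_cutoff = cutoff),
            class = "uq_failure_result")
}

#' @export
print.uq_failure_result <- function(x, ...) {
  cat(sprintf("<uq_failure_result> %s / %s: n = %d, failures = %d\n",
              x$family, x$region, nrow(x$pairs), sum(x$pairs$failure_label)))
  cat(sprintf("  rho %.3f  AUC %.3f  Youden accuracy %.3f (cutoff %.2f)\n",
              x$spearman_rho, x$auc_roc, x$youden_accuracy, x$dice_cutoff))
  invisible(x)
}

#' Tidy method: per-subject score/Dice/label pairs
#' @param x a `uq_failure_result`.
#' @param ... unused.
#' @method tidy uq_failure_result
#' @export
tidy.uq_failure_result <- function(x, ...) {
  dplyr::mutate(x$pairs, region = x$region, family = x$family)
}

#' Glance method: one-row metric summary
#' @param x a `uq_failure_result`.
#' @param ... unused.
#' @method glance uq_failure_result
#' @export
glance.uq_failure_result <- function(x, ...) {
  tibble::tibble(region = x$region, family = x$family,
                 n = nrow(x$pairs), n_failed = sum(x$pairs$failure_label),
                 spearman_rho = x$spearman_rho, auc_roc = x$auc_roc,
                 youden_threshold = x$youden_threshold,
                 youden_accuracy = x$youden_accuracy,
                 dice_cutoff = x$dice_cutoff)
}
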