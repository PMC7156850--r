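# Subject-level aggregation of voxel-wise uncertainty: the mean family,
# the prior-knowledge weighting x reducer family, the automatic feature
# family, and the random-forest Dice regressor built on top of them.

#' Negative mean uncertainty inside a mask
#'
#' The simplest subject-level aggregate: minus the mean uncertainty over
#' the evaluation mask, so that larger values predict better segmentations.
#'
#' @param q an `uq_uncertainty` or bare volume.
#' @param mask evaluation mask (non-empty).
#' @return scalar in \[-1, 0\].
#' @export
mean_aggregate <- function(q, mask) {
  qv <- if (inherits(q, "uq_uncertainty")) q$values else q
  mask <- as_mask(mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  -mean(qv[mask])
}

#' Three-voxel boundary band of a segmentation
#'
#' Voxels at the predicted segmentation surface plus the immediate inner
#' and outer shells (face-connected), i.e. the three-voxel-wide band used
#' to mask out the boundary uncertainty that even good segmentations
#' inherently carry.
#'
#' @param pred binary volume.
#' @return logical volume; empty input gives an empty band.
#' @export
boundary_band <- function(pred) {
  assert_binary(pred)
  pred <- as_mask(pred)
  if (!any(pred)) return(array(FALSE, dim(pred)))
  # work inside the region's bounding box; the band cannot extend further
  # than one voxel beyond it
  idx <- which(pred, arr.ind = TRUE)
  win <- lapply(1:3, function(ax)
    max(1L, min(idx[, ax]) - 2L):min(dim(pred)[ax], max(idx[, ax]) + 2L))
  pw <- pred[win[[1]], win[[2]], win[[3]], drop = FALSE]
  inner <- pw & !erode1(pw)          # surface voxels
  band <- inner | (dilate1(inner) & !inner)  # + inner/outer face shells
  out <- array(FALSE, dim(pred))
  out[win[[1]], win[[2]], win[[3]]] <- band
  out
}

#' Euclidean distance (mm) to the predicted boundary
#'
#' Unsigned distance from every voxel to the nearest surface voxel of the
#' predicted segmentation.
#'
#' @param pred binary volume (non-empty).
#' @param spacing voxel size in mm.
#' @return numeric volume of distances.
#' @export
boundary_distance <- function(pred, spacing = c(1, 1, 1)) {
  pred <- as_mask(pred)
  if (!any(pred)) stop("empty prediction has no boundary", call. = FALSE)
  surface <- pred & !erode1(pred)
  distance_transform(surface, spacing)
}

pk_feature_names <- function() {
  as.vector(outer(c("boundary_masked", "distance_weighted_masked",
                    "volume_normalized"),
                  c("mean", "sum", "logsum"), paste, sep = "_"))
}

#' Prior-knowledge weighted aggregation features
#'
#' Nine subject-level features: three boundary-deemphasizing weightings of
#' the uncertainty map, each reduced by mean (over the evaluation mask),
#' sum and `logsum = log(1 + sum)`:
#' * `boundary_masked_*` — uncertainty zeroed on the 3-voxel
#'   [boundary_band()] of the prediction;
#' * `distance_weighted_masked_*` — uncertainty multiplied by the Euclidean
#'   distance (mm) to the predicted boundary, which up-weights uncertainty
#'   far from the boundary and vanishes on it (hence "masked");
#' * `volume_normalized_*` — uncertainty divided by the predicted
#'   segmentation volume in voxels.
#'
#' An empty prediction leaves the distance- and volume-based weightings
#' undefined; those features are returned as `NA` and are imputed (0 plus
#' a missingness indicator) by [fit_dice_regressor()].
#'
#' @param q an `uq_uncertainty` or bare volume.
#' @param pred predicted binary volume.
#' @param mask evaluation mask (brain mask).
#' @param spacing voxel size in mm.
#' @return named numeric vector of 9 features.
#' @export
prior_knowledge_features <- function(q, pred, mask, spacing = c(1, 1, 1)) {
  qv <- if (inherits(q, "uq_uncertainty")) q$values else q
  pred <- as_mask(pred); mask <- as_mask(mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  assert_same_shape(qv, pred, "q", "pred")
  reduce3 <- function(w) {
    s <- sum(w[mask])
    c(mean = s / sum(mask), sum = s, logsum = log1p(s))
  }
  w1 <- qv
  w1[boundary_band(pred)] <- 0
  out <- c(boundary_masked = reduce3(w1))
  if (any(pred)) {
    d <- boundary_distance(pred, spacing)
    out <- c(out, distance_weighted_masked = reduce3(qv * d),
             volume_normalized = reduce3(qv / sum(pred)))
  } else {
    nas <- c(mean = NA_real_, sum = NA_real_, logsum = NA_real_)
    out <- c(out, distance_weighted_masked = nas, volume_normalized = nas)
  }
  names(out) <- sub("\\.", "_", names(out))
  out
}

#' Subject-level feature table for a cohort
#'
#' Materializes each subject once and extracts, per region, the aggregates
#' of all requested families plus the true Dice coefficient and split.
#' Uncertainty is the stored map or the entropy of the probability map.
#'
#' @param cohort a `uq_cohort`.
#' @param regions region names.
#' @param thresholds named list region -> `uq_threshold` (needed for the
#'   automatic family).
#' @param families subset of `c("mean", "prior_knowledge", "automatic")`.
#' @return tibble in long-wide form: subject_id, split, region, family,
#'   true_dice, then one column per feature (NA where not applicable).
#' @export
cohort_features <- function(cohort, regions = NULL, thresholds = NULL,
                            families = c("mean", "prior_knowledge",
                                         "automatic")) {
  if (is.null(regions)) regions <- cohort_regions(cohort)
  families <- match.arg(families, several.ok = TRUE)
  if ("automatic" %in% families && is.null(thresholds))
    stop("automatic features need the frozen U-E thresholds", call. = FALSE)
  rows <- list()
  for (i in seq_len(n_subjects(cohort))) {
    s <- cohort_subject(cohort, i)
    for (r in regions) {
      q <- subject_uncertainty(s, r)
      dice <- dice_coefficient(s$pred_labels[[r]], s$gt_labels[[r]])
      base <- tibble::tibble(subject_id = s$subject_id, split = s$split,
                             region = r, true_dice = dice)
      if ("mean" %in% families) {
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          base, family = "mean",
          tibble::as_tibble_row(c(neg_mean_uncertainty =
                                    mean_aggregate(q, s$brain_mask))))
      }
      if ("prior_knowledge" %in% families) {
        f <- prior_knowledge_features(q, s$pred_labels[[r]], s$brain_mask,
                                      s$spacing)
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          base, family = "prior_knowledge", tibble::as_tibble_row(f))
      }
      if ("automatic" %in% families) {
        f <- automatic_features(q, thresholds[[r]], s$spacing, s$brain_mask)
        rows[[length(rows) + 1L]] <- dplyr::bind_cols(
          base, family = "automatic", tibble::as_tibble_row(f))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Fit a random-forest Dice regressor on subject features
#'
#' Trains a random forest that predicts the per-subject Dice coefficient
#' from aggregated uncertainty features. Missing features (empty
#' segmentations or empty thresholded maps) are imputed with 0 and flagged
#' through added `miss_<name>` indicator columns, so degenerate subjects
#' cannot crash cohort-level training. The fit is deterministic for a
#' given seed.
#'
#' @param features data frame / tibble of numeric feature columns (rows =
#'   training subjects). Non-feature columns (`subject_id`, `split`,
#'   `region`, `family`, `true_dice`) are dropped automatically.
#' @param dice numeric vector of true Dice values (same order as rows);
#'   if `NULL`, taken from a `true_dice` column.
#' @param ntree number of trees (default 500).
#' @param seed RNG seed recorded in the model.
#' @param ... further arguments passed to [randomForest::randomForest()].
#' @return object of class `uq_dice_regressor`.
#' @export
fit_dice_regressor <- function(features, dice = NULL, ntree = 500,
                               seed = 1L, ...) {
  features <- tibble::as_tibble(features)
  if (is.null(dice)) {
    if (!"true_dice" %in% names(features))
      stop("no `dice` given and no `true_dice` column", call. = FALSE)
    dice <- features$true_dice
  }
  meta_cols <- intersect(c("subject_id", "split", "region", "family",
                           "true_dice"), names(features))
  x <- features[, setdiff(names(features), meta_cols), drop = FALSE]
  x <- x[, vapply(x, is.numeric, logical(1)), drop = FALSE]
  # drop features absent for this family (all-NA columns)
  x <- x[, !vapply(x, function(v) all(is.na(v)), logical(1)), drop = FALSE]
  if (nrow(x) < 10) stop("need at least 10 training subjects", call. = FALSE)
  if (sd(dice) == 0)
    stop("constant Dice target; the regressor cannot be trained", call. = FALSE)
  # impute + flag missing
  miss_cols <- names(x)[vapply(x, anyNA, logical(1))]
  for (nm in miss_cols) {
    x[[paste0("miss_", nm)]] <- as.numeric(is.na(x[[nm]]))
    x[[nm]][is.na(x[[nm]])] <- 0
  }
  fit <- withr::with_seed(seed,
    randomForest::randomForest(x = as.data.frame(x), y = dice,
                               ntree = ntree, importance = TRUE, ...))
  imp <- randomForest::importance(fit, type = 1)[, 1]
  structure(list(model = fit, feature_names = names(x),
                 importances = imp, seed = seed, ntree = ntree,
                 oob_mse = fit$mse[ntree], oob_rsq = fit$rsq[ntree]),
            class = "uq_dice_regressor")
}

#' Predict Dice for new subjects
#'
#' @param object a `uq_dice_regressor`.
#' @param newdata feature table with the training feature columns.
#' @param ... unused.
#' @return numeric vector of predicted Dice values, clipped to \[0, 1\].
#' @export
predict.uq_dice_regressor <- function(object, newdata, ...) {
  newdata <- tibble::as_tibble(newdata)
  meta_cols <- intersect(c("subject_id", "split", "region", "family",
                           "true_dice"), names(newdata))
  x <- newdata[, setdiff(names(newdata), meta_cols), drop = FALSE]
  base_feats <- setdiff(object$feature_names,
                        grep("^miss_", object$feature_names, value = TRUE))
  missing_feats <- setdiff(base_feats, names(x))
  if (length(missing_feats) > 0)
    stop("feature name mismatch; missing: ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  for (nm in grep("^miss_", object$feature_names, value = TRUE)) {
    src <- sub("^miss_", "", nm)
    x[[nm]] <- as.numeric(is.na(x[[src]]))
  }
  for (nm in base_feats) x[[nm]][is.na(x[[nm]])] <- 0
  x <- x[, object$feature_names, drop = FALSE]
  p <- predict(object$model, newdata = as.data.frame(x))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
print.uq_dice_regressor <- function(x, ...) {
  cat(sprintf("<uq_dice_regressor> %d features, %d trees, OOB R^2 %.3f\n",
              length(x$feature_names), x$ntree, x$oob_rsq))
  invisible(x)
}

#' Tidy method: per-feature importances
#' @param x a `uq_dice_regressor`.
#' @param ... unused.
#' @method tidy uq_dice_regressor
#' @export
tidy.uq_dice_regressor <- function(x, ...) {
  tibble::tibble(feature = names(x$importances),
                 importance = unname(x$importances)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' Glance method: one-row fit summary
#' @param x a `uq_dice_regressor`.
#' @param ... unused.
#' @method glance uq_dice_regressor
#' @export
glance.uq_dice_regressor <- function(x, ...) {
  tibble::tibble(n_features = length(x$feature_names), ntree = x$ntree,
                 oob_mse = x$oob_mse, oob_rsq = x$oob_rsq, seed = x$seed)
}

#' Accumulate feature-importance ranks over several regressors
#'
#' Ranks features within each model by decreasing importance (rank 1 =
#' most important), sums the ranks across models, and orders features by
#' ascending total rank. Ties are broken alphabetically. All models must
#' share one feature set.
#'
#' @param models list of `uq_dice_regressor`.
#' @return tibble: feature, total_rank, mean_rank, in rank order.
#' @export
rank_accumulate_importance <- function(models) {
  stopifnot(length(models) >= 1)
  feats <- sort(names(models[[1]]$importances))
  for (m in models) {
    if (!identical(sort(names(m$importances)), feats))
      stop("models have mismatched feature sets", call. = FALSE)
  }
  ranks <- vapply(models, function(m) {
    imp <- m$importances[feats]
    rank(-imp, ties.method = "average")
  }, numeric(length(feats)))
  ranks <- matrix(ranks, nrow = length(feats))
  total <- rowSums(ranks)
  tibble::tibble(feature = feats, total_rank = total,
                 mean_rank = total / length(models)) |>
    dplyr::arrange(.data$total_rank, .data$feature)
}
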