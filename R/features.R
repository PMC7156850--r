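# Automatically extracted features of a thresholded uncertainty map:
# shape, first-order and gray-level run-length descriptors, in the spirit
# of radiomics feature panels. Discretization and directions are pinned so
# the panel is deterministic.

#' Sphericity of a binary region
#'
#' `pi^(1/3) (6 V)^(2/3) / A` with volume V (mm^3) and mesh surface area A
#' (mm^2); 1 for a perfect sphere, lower for elongated or sheet-like
#' regions such as the thin uncertainty rim of a successful segmentation.
#'
#' @param mask logical volume.
#' @param spacing voxel size in mm.
#' @return scalar (NA for an empty mask).
#' @export
sphericity <- function(mask, spacing = c(1, 1, 1)) {
  mask <- as_mask(mask)
  if (!any(mask)) return(NA_real_)
  V <- sum(mask) * prod(spacing)
  A <- surface_area(mask, spacing)
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

# Pooled gray-level run-length matrix over the three axis directions.
# `levels` is an integer array (0 = outside ROI, breaks runs).
glrlm <- function(levels) {
  runs_level <- integer(0); runs_len <- integer(0)
  d <- dim(levels)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(levels, perm), nrow = d[ax])
    # separator row so runs cannot span adjacent lines
    v <- as.vector(rbind(m, 0L))
    r <- rle(v)
    keep <- r$values > 0L
    runs_level <- c(runs_level, r$values[keep])
    runs_len <- c(runs_len, r$lengths[keep])
  }
  list(level = runs_level, length = runs_len)
}

# run-length feature set from a run list
glrlm_features <- function(runs) {
  n_runs <- length(runs$length)
  if (n_runs == 0)
    return(c(rln = NA_real_, gln = NA_real_, sre = NA_real_, lre = NA_real_,
             run_percentage = NA_real_))
  len_tab <- tapply(rep(1, n_runs), runs$length, sum)  # sum_i R(i,j) per j
  lev_tab <- tapply(rep(1, n_runs), runs$level, sum)   # sum_j R(i,j) per i
  j <- as.numeric(names(len_tab))
  c(rln = sum(len_tab^2) / n_runs,
    gln = sum(lev_tab^2) / n_runs,
    sre = sum(len_tab / j^2) / n_runs,
    lre = sum(len_tab * j^2) / n_runs,
    run_percentage = n_runs / sum(runs$length))
}

#' Run-length non-uniformity of a discretized map
#'
#' `RLN = sum_j (sum_i R(i,j))^2 / N_runs` over the gray-level run-length
#' matrix R pooled over the three axis directions. Low values mean the run
#' lengths are homogeneous.
#'
#' @param levels integer 3D array of gray levels (0 = outside, breaks runs).
#' @return scalar.
#' @export
run_length_non_uniformity <- function(levels) {
  assert_volume(levels)
  unname(glrlm_features(glrlm(levels))["rln"])
}

#' Discretize an uncertainty map into fixed-width gray levels
#'
#' Fixed bin width 0.05 on \[0, 1\] (20 levels); voxels outside `roi` get
#' level 0. Pinning the discretization keeps run-length features
#' deterministic across cohorts.
#'
#' @param q numeric volume in \[0, 1\].
#' @param roi logical volume.
#' @param bin_width scalar, default 0.05.
#' @return integer array of levels.
#' @export
discretize_map <- function(q, roi, bin_width = 0.05) {
  lev <- pmin(pmax(ceiling(q / bin_width), 1L), ceiling(1 / bin_width))
  out <- array(0L, dim(q))
  roi <- as_mask(roi)
  out[roi] <- as.integer(lev[roi])
  out
}

first_order_features <- function(x) {
  if (length(x) == 0)
    return(c(fo_mean = NA_real_, fo_variance = NA_real_, fo_entropy = NA_real_,
             fo_min = NA_real_, fo_p10 = NA_real_, fo_p25 = NA_real_,
             fo_median = NA_real_, fo_p75 = NA_real_, fo_p90 = NA_real_,
             fo_max = NA_real_, fo_energy = NA_real_, fo_rms = NA_real_))
  qs <- unname(quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE))
  # histogram entropy at the pinned 0.05 bin width
  p <- tabulate(pmin(pmax(ceiling(x / 0.05), 1L), 20L), nbins = 20L)
  p <- p[p > 0] / length(x)
  c(fo_mean = mean(x),
    fo_variance = if (length(x) > 1) stats::var(x) else 0,
    fo_entropy = -sum(p * log2(p)),
    fo_min = min(x), fo_p10 = qs[1], fo_p25 = qs[2], fo_median = qs[3],
    fo_p75 = qs[4], fo_p90 = qs[5], fo_max = max(x),
    fo_energy = sum(x^2), fo_rms = sqrt(mean(x^2)))
}

shape_features <- function(roi, spacing) {
  if (!any(roi)) {
    return(c(shape_volume_voxels = NA_real_, shape_volume_mm3 = NA_real_,
             shape_surface_area_mm2 = NA_real_, shape_sphericity = NA_real_,
             shape_surface_volume_ratio = NA_real_))
  }
  V_vox <- sum(roi)
  V <- V_vox * prod(spacing)
  A <- surface_area(roi, spacing)
  c(shape_volume_voxels = V_vox, shape_volume_mm3 = V,
    shape_surface_area_mm2 = A,
    shape_sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    shape_surface_volume_ratio = A / V)
}

#' Automatic features of a thresholded uncertainty map
#'
#' Binarizes the uncertainty map at the method's U-E-selected threshold and
#' extracts shape features of the thresholded region, first-order features
#' of the uncertainty values inside it, and run-length features of the
#' fixed-bin discretized map. The panel is configurable; the defaults keep
#' the named key features (volume, surface area, sphericity, first-order
#' mean/variance/entropy/percentiles, run-length non-uniformity). An empty
#' thresholded region yields an all-missing row, flagged via `roi_empty`.
#'
#' @param q an `uq_uncertainty` or bare \[0, 1\] volume.
#' @param threshold scalar from [select_threshold()] (frozen on validation).
#' @param spacing voxel size in mm.
#' @param mask optional support mask (brain mask).
#' @return named numeric vector of features.
#' @export
automatic_features <- function(q, threshold, spacing = c(1, 1, 1),
                               mask = NULL) {
  qv <- if (inherits(q, "uq_uncertainty")) q$values else q
  if (inherits(threshold, "uq_threshold")) threshold <- threshold$threshold
  stopifnot(threshold > 0, threshold < 1)
  roi <- qv >= threshold
  if (!is.null(mask)) roi <- roi & as_mask(mask)
  feats <- c(shape_features(roi, spacing),
             first_order_features(qv[roi]),
             glrlm_features(glrlm(discretize_map(qv, roi))),
             roi_empty = as.numeric(!any(roi)))
  feats
}
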