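# Cohort data model: subjects, hierarchical tumor labels, validation.

REGIONS <- c("WT", "TC", "ET")

#' Default sub-compartment label codes
#'
#' Integer codes used in label volumes for the tumor sub-compartments:
#' necrosis/non-enhancing core (NCR/NET), edema (ED) and enhancing tumor
#' (ET). The defaults follow the common brain-tumor convention
#' (1 = NCR/NET, 2 = ED, 4 = ET) and can be overridden wherever a coded
#' label volume is consumed.
#'
#' @return named integer vector with entries `ncr_net`, `ed`, `et`.
#' @export
subcompartment_codes <- function() {
  c(ncr_net = 1L, ed = 2L, et = 4L)
}

#' Combine sub-compartment labels into hierarchical tumor regions
#'
#' Builds the three nested regions from an integer-coded label volume:
#' whole tumor (WT) is the union of all sub-compartments, tumor core (TC)
#' is enhancing tumor plus necrosis/non-enhancing core, and enhancing tumor
#' (ET) is the ET sub-compartment alone. The outputs always satisfy
#' ET is contained in TC is contained in WT.
#'
#' @param labels integer-coded 3D label volume containing only 0 and the
#'   configured codes.
#' @param codes named vector of sub-compartment codes
#'   (see [subcompartment_codes()]).
#' @return named list of logical volumes `WT`, `TC`, `ET`.
#' @export
combine_hierarchical_labels <- function(labels, codes = subcompartment_codes()) {
  assert_volume(labels)
  stopifnot(all(c("ncr_net", "ed", "et") %in% names(codes)))
  present <- unique(as.vector(labels))
  unknown <- setdiff(present, c(0, unname(codes)))
  if (length(unknown) > 0)
    stop("unknown label code(s): ", paste(sort(unknown), collapse = ", "),
         call. = FALSE)
  et  <- array(labels == codes[["et"]], dim(labels))
  ncr <- array(labels == codes[["ncr_net"]], dim(labels))
  ed  <- array(labels == codes[["ed"]], dim(labels))
  list(WT = et | ncr | ed, TC = et | ncr, ET = et)
}

#' Decompose hierarchical regions back into sub-compartment codes
#'
#' Inverse of [combine_hierarchical_labels()] on valid nested inputs:
#' NCR/NET = TC minus ET, ED = WT minus TC.
#'
#' @param regions named list with logical volumes `WT`, `TC`, `ET`.
#' @param codes named vector of sub-compartment codes.
#' @return integer-coded 3D label volume.
#' @export
decompose_hierarchical_labels <- function(regions, codes = subcompartment_codes()) {
  stopifnot(all(REGIONS %in% names(regions)))
  wt <- as_mask(regions$WT); tc <- as_mask(regions$TC); et <- as_mask(regions$ET)
  if (any(et & !tc) || any(tc & !wt))
    stop("regions do not satisfy ET ⊆ TC ⊆ WT", call. = FALSE)
  out <- array(0L, dim(wt))
  out[wt & !tc] <- codes[["ed"]]
  out[tc & !et] <- codes[["ncr_net"]]
  out[et] <- codes[["et"]]
  out
}

#' Construct a per-subject record
#'
#' Bundles all volumes of one subject: ground-truth and predicted region
#' masks, optional foreground-probability maps, optional uncertainty maps,
#' the brain mask, voxel spacing and split assignment. All volumes must
#' share one shape; labels must be supported inside the brain mask.
#'
#' @param subject_id character scalar.
#' @param gt_labels,pred_labels named lists of binary volumes per region.
#' @param brain_mask logical volume (defaults to all-ones if `NULL`).
#' @param prob_maps optional named list of probability volumes per region.
#' @param uncertainty_maps optional named list of [uncertainty_map()]
#'   objects (or bare volumes, taken as entropy-derived).
#' @param spacing per-axis physical voxel size in mm.
#' @param split one of `"train"`, `"validation"`, `"test"`.
#' @param check_hierarchy enforce ET is contained in TC is contained in WT on
#'   `gt_labels` (predictions are deliberately not repaired; see vignette).
#' @return object of class `uq_subject`.
#' @export
subject_record <- function(subject_id, gt_labels, pred_labels,
                           brain_mask = NULL, prob_maps = NULL,
                           uncertainty_maps = NULL,
                           spacing = c(1, 1, 1),
                           split = c("train", "validation", "test"),
                           check_hierarchy = TRUE) {
  split <- match.arg(split)
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  ref <- gt_labels[[1]]
  assert_volume(ref, "gt_labels[[1]]")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim(ref))
  brain_mask <- as_mask(brain_mask)
  assert_same_shape(ref, brain_mask, "gt labels", "brain_mask")

  gt_labels <- lapply(gt_labels, as_mask)
  pred_labels <- lapply(pred_labels, as_mask)
  for (nm in names(gt_labels)) {
    assert_same_shape(ref, gt_labels[[nm]], "gt_labels[[1]]", paste0("gt ", nm))
    if (any(gt_labels[[nm]] & !brain_mask))
      stop("gt labels for ", nm, " extend outside the brain mask", call. = FALSE)
  }
  for (nm in names(pred_labels)) {
    assert_same_shape(ref, pred_labels[[nm]], "gt_labels[[1]]", paste0("pred ", nm))
    if (any(pred_labels[[nm]] & !brain_mask))
      stop("pred labels for ", nm, " extend outside the brain mask", call. = FALSE)
  }
  if (check_hierarchy && all(REGIONS %in% names(gt_labels))) {
    if (any(gt_labels$ET & !gt_labels$TC) || any(gt_labels$TC & !gt_labels$WT))
      stop("gt labels violate ET ⊆ TC ⊆ WT", call. = FALSE)
  }
  if (!is.null(prob_maps)) {
    for (nm in names(prob_maps)) {
      assert_same_shape(ref, prob_maps[[nm]], "gt_labels[[1]]", paste0("prob ", nm))
      assert_probability(prob_maps[[nm]], paste0("prob_maps$", nm))
    }
  }
  if (!is.null(uncertainty_maps)) {
    nms <- names(uncertainty_maps)
    uncertainty_maps <- lapply(nms, function(nm) {
      u <- uncertainty_maps[[nm]]
      if (!inherits(u, "uq_uncertainty"))
        u <- uncertainty_map(u, provenance = "native", region = nm)
      assert_same_shape(ref, u$values, "gt_labels[[1]]", paste0("uncertainty ", nm))
      u
    })
    names(uncertainty_maps) <- nms
  }
  structure(
    list(subject_id = subject_id, spacing = as.numeric(spacing),
         brain_mask = brain_mask, gt_labels = gt_labels,
         pred_labels = pred_labels, prob_maps = prob_maps,
         uncertainty_maps = uncertainty_maps, split = split),
    class = "uq_subject")
}

#' @export
print.uq_subject <- function(x, ...) {
  d <- dim(x$brain_mask)
  cat(sprintf("<uq_subject> %s  grid %s  spacing %s mm  split %s\n",
              x$subject_id, paste(d, collapse = "x"),
              paste(x$spacing, collapse = "x"), x$split))
  cat("  regions:", paste(names(x$gt_labels), collapse = ", "), "\n")
  invisible(x)
}

subject_regions <- function(subject) names(subject$gt_labels)
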