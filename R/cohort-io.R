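# Reading and writing subjects/cohorts: NIfTI volumes + CSV manifest.
#
# A cohort manifest is a CSV with columns subject_id, split and one path
# column per volume role: brain_mask, gt_<REGION>, pred_<REGION>,
# prob_<REGION>, unc_<REGION> (probability / uncertainty columns optional).
# A gt_labels column holding a single integer-coded volume is also accepted
# and combined into hierarchical regions on load.

read_volume <- function(path) {
  v <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(v)[1:3]
  a <- array(as.numeric(v), dim(v)[1:3])
  attr(a, "spacing") <- sp
  a
}

write_volume <- function(a, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.numeric(a), dim(a)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load one subject from volume files
#'
#' Reads NIfTI volumes, validates shapes and spacings against each other,
#' optionally combines an integer-coded sub-compartment volume into the
#' hierarchical regions, and returns a [subject_record()].
#'
#' @param paths named list/vector of file paths. Recognized names:
#'   `brain_mask`, `gt_labels` (coded volume) or `gt_<REGION>`,
#'   `pred_<REGION>`, `prob_<REGION>`, `unc_<REGION>`.
#' @param subject_id character scalar.
#' @param split split assignment.
#' @param codes sub-compartment codes used when `gt_labels` is coded.
#' @param missing_mask what to do when no brain mask path is given:
#'   `"all_ones"` (documented fallback) or `"error"`.
#' @return a `uq_subject`.
#' @export
load_subject <- function(paths, subject_id, split = "test",
                         codes = subcompartment_codes(),
                         missing_mask = c("all_ones", "error")) {
  missing_mask <- match.arg(missing_mask)
  paths <- as.list(paths)
  vols <- lapply(paths, read_volume)

  ref_name <- names(vols)[1]
  ref <- vols[[1]]
  for (nm in names(vols)) {
    if (!identical(dim(vols[[nm]]), dim(ref)))
      stop(sprintf("shape mismatch between `%s` (%s) and `%s` (%s)",
                   ref_name, paste(dim(ref), collapse = "x"),
                   nm, paste(dim(vols[[nm]]), collapse = "x")), call. = FALSE)
    sp1 <- attr(ref, "spacing"); sp2 <- attr(vols[[nm]], "spacing")
    if (max(abs(sp1 - sp2)) > 1e-4)
      stop(sprintf("spacing mismatch between `%s` and `%s`", ref_name, nm),
           call. = FALSE)
  }
  spacing <- attr(ref, "spacing")

  if ("gt_labels" %in% names(vols)) {
    gt <- combine_hierarchical_labels(array(as.integer(round(vols$gt_labels)),
                                            dim(ref)), codes)
  } else {
    gt_names <- grep("^gt_", names(vols), value = TRUE)
    gt <- lapply(vols[gt_names], as_mask)
    names(gt) <- sub("^gt_", "", gt_names)
  }
  pred_names <- grep("^pred_", names(vols), value = TRUE)
  pred <- lapply(vols[pred_names], as_mask)
  names(pred) <- sub("^pred_", "", pred_names)

  prob_names <- grep("^prob_", names(vols), value = TRUE)
  prob <- NULL
  if (length(prob_names) > 0) {
    prob <- lapply(vols[prob_names], function(v) {
      attr(v, "spacing") <- NULL
      v
    })
    names(prob) <- sub("^prob_", "", prob_names)
    for (nm in names(prob)) assert_probability(prob[[nm]], paste0("prob_", nm))
  }
  unc_names <- grep("^unc_", names(vols), value = TRUE)
  unc <- NULL
  if (length(unc_names) > 0) {
    unc <- lapply(vols[unc_names], function(v) {
      attr(v, "spacing") <- NULL
      v
    })
    names(unc) <- sub("^unc_", "", unc_names)
  }
  if ("brain_mask" %in% names(vols)) {
    mask <- as_mask(vols$brain_mask)
  } else if (missing_mask == "all_ones") {
    mask <- array(TRUE, dim(ref))
  } else {
    stop("no brain mask supplied", call. = FALSE)
  }
  subject_record(subject_id, gt_labels = gt, pred_labels = pred,
                 brain_mask = mask, prob_maps = prob, uncertainty_maps = unc,
                 spacing = spacing, split = split)
}

#' Write one subject to a directory as NIfTI volumes
#'
#' @param subject a `uq_subject`.
#' @param dir output directory (created if needed).
#' @return named list of written file paths (the manifest row).
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- subject$spacing
  p <- function(role) file.path(dir, paste0(subject$subject_id, "_", role, ".nii.gz"))
  out <- list()
  out$brain_mask <- write_volume(subject$brain_mask * 1, p("brain_mask"), sp)
  for (nm in names(subject$gt_labels))
    out[[paste0("gt_", nm)]] <- write_volume(subject$gt_labels[[nm]] * 1,
                                             p(paste0("gt_", nm)), sp)
  for (nm in names(subject$pred_labels))
    out[[paste0("pred_", nm)]] <- write_volume(subject$pred_labels[[nm]] * 1,
                                               p(paste0("pred_", nm)), sp)
  for (nm in names(subject$prob_maps))
    out[[paste0("prob_", nm)]] <- write_volume(subject$prob_maps[[nm]],
                                               p(paste0("prob_", nm)), sp)
  for (nm in names(subject$uncertainty_maps)) {
    u <- subject$uncertainty_maps[[nm]]
    out[[paste0("unc_", nm)]] <- write_volume(u$values, p(paste0("unc_", nm)), sp)
    sidecar <- file.path(dir, paste0(subject$subject_id, "_unc_", nm, ".json"))
    jsonlite::write_json(list(provenance = u$provenance, region = u$region),
                         sidecar, auto_unbox = TRUE)
  }
  out
}

#' Write a cohort to disk (volumes + manifest CSV)
#'
#' @param cohort a `uq_cohort` (see [generate_cohort()] or [cohort_from_manifest()]).
#' @param dir output directory.
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(seq_len(n_subjects(cohort)), function(i) {
    s <- cohort_subject(cohort, i)
    paths <- write_subject(s, file.path(dir, s$subject_id))
    # store paths relative to the manifest so cohort directories move freely
    paths <- lapply(paths, function(p)
      file.path(s$subject_id, basename(p)))
    c(list(subject_id = s$subject_id, split = s$split), paths)
  })
  manifest <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  extra <- cohort$manifest
  if (!is.null(extra)) {
    keep <- setdiff(names(extra), names(manifest))
    manifest <- dplyr::bind_cols(manifest, extra[, keep, drop = FALSE])
  }
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Cohort backed by a manifest CSV on disk
#'
#' Subjects are loaded lazily: [cohort_subject()] reads one subject's
#' volumes when asked, so arbitrarily large cohorts fit in memory.
#'
#' @param manifest_path path to a manifest CSV.
#' @param codes sub-compartment codes for coded gt volumes.
#' @return object of class `uq_cohort`.
#' @export
cohort_from_manifest <- function(manifest_path, codes = subcompartment_codes()) {
  manifest <- tibble::as_tibble(read.csv(manifest_path, stringsAsFactors = FALSE))
  stopifnot(all(c("subject_id", "split") %in% names(manifest)))
  if (anyDuplicated(manifest$subject_id))
    stop("duplicate subject_id in manifest", call. = FALSE)
  structure(list(source = "manifest", manifest = manifest,
                 dir = dirname(manifest_path), codes = codes),
            class = "uq_cohort")
}

#' Number of subjects in a cohort
#' @param cohort a `uq_cohort`.
#' @export
n_subjects <- function(cohort) nrow(cohort$manifest)

#' Materialize one subject of a cohort
#'
#' For manifest-backed cohorts this reads the subject's volumes from disk;
#' for synthetic cohorts it regenerates the subject deterministically from
#' the cohort specification and master seed.
#'
#' @param cohort a `uq_cohort`.
#' @param i subject index (1-based) or subject_id.
#' @return a `uq_subject`.
#' @export
cohort_subject <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$manifest$subject_id)
  stopifnot(!is.na(i), i >= 1, i <= n_subjects(cohort))
  row <- cohort$manifest[i, ]
  if (cohort$source == "synthetic") {
    return(synthesize_subject(cohort$spec, i, row))
  }
  path_cols <- setdiff(names(row), c("subject_id", "split", "tau",
                                     "failure_mode",
                                     grep("^true_dice", names(row), value = TRUE)))
  paths <- as.list(row[path_cols])
  paths <- paths[!vapply(paths, function(p) is.na(p) || p == "", logical(1))]
  paths <- lapply(paths, function(p)
    if (file.exists(p)) p else file.path(cohort$dir, p))
  load_subject(paths, subject_id = row$subject_id, split = row$split,
               codes = cohort$codes)
}

#' Region names of a cohort
#' @param cohort a `uq_cohort`.
#' @export
cohort_regions <- function(cohort) {
  if (cohort$source == "synthetic") return(cohort$spec$regions)
  if ("gt_labels" %in% names(cohort$manifest)) return(REGIONS)
  sub("^gt_", "", grep("^gt_", names(cohort$manifest), value = TRUE))
}

#' @export
print.uq_cohort <- function(x, ...) {
  cat(sprintf("<uq_cohort> %d subjects (%s)\n", n_subjects(x), x$source))
  print(table(x$manifest$split))
  invisible(x)
}
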