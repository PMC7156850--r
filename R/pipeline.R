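# Pipeline orchestration: configuration, the three analysis stages, and
# report files. Each stage writes CSV tables plus a resolved-config JSON
# so any output directory fully documents how to reproduce itself.

config_error <- function(msg) rlang::abort(msg, class = "uqseg_config_error")
data_error <- function(msg) rlang::abort(msg, class = "uqseg_data_error")

#' Load and validate a pipeline configuration
#'
#' The configuration is a flat YAML file. Recognized keys:
#' `cohort` (either `manifest: <path>` or `synthetic: <cohort_spec args>`),
#' `regions`, `bins`, `calibration_tolerance`, `families`,
#' `regressor: {ntree, seed}`, `dice_cutoffs: {<region>: <value>}`,
#' `output_dir`. Validation happens before any computation.
#'
#' @param path YAML file path, or a list already in memory.
#' @return validated config (class `uq_config`).
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) config_error("config must be a YAML mapping")
  if (is.null(cfg$cohort) ||
      (is.null(cfg$cohort$manifest) && is.null(cfg$cohort$synthetic)))
    config_error("config needs cohort.manifest or cohort.synthetic")
  if (!is.null(cfg$cohort$synthetic)) {
    # YAML mappings arrive as lists; cohort_spec wants (named) vectors
    syn <- lapply(cfg$cohort$synthetic, function(x)
      if (is.list(x)) unlist(x) else x)
    spec <- tryCatch(do.call(cohort_spec, syn),
                     error = function(e) config_error(conditionMessage(e)))
    cfg$cohort$spec <- spec
  }
  cfg$bins <- cfg$bins %||% 10
  if (cfg$bins < 2) config_error("bins must be >= 2")
  cfg$calibration_tolerance <- cfg$calibration_tolerance %||% 0.01
  cfg$families <- cfg$families %||% c("mean", "prior_knowledge", "automatic")
  bad <- setdiff(cfg$families, c("mean", "prior_knowledge", "automatic"))
  if (length(bad) > 0)
    config_error(paste("unknown families:", paste(bad, collapse = ", ")))
  cfg$regressor <- utils::modifyList(list(ntree = 500, seed = 7L),
                                     cfg$regressor %||% list())
  if (!is.null(cfg$dice_cutoffs)) {
    cuts <- unlist(cfg$dice_cutoffs)
    if (any(cuts <= 0 | cuts >= 1))
      config_error("dice_cutoffs must lie in (0, 1)")
  }
  cfg$output_dir <- cfg$output_dir %||% "uqseg_output"
  structure(cfg, class = "uq_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_cohort <- function(cfg) {
  if (!is.null(cfg$cohort$manifest)) {
    if (!file.exists(cfg$cohort$manifest))
      data_error(paste("manifest not found:", cfg$cohort$manifest))
    cohort_from_manifest(cfg$cohort$manifest)
  } else {
    generate_cohort(cfg$cohort$spec, compute_dice = FALSE)
  }
}

write_resolved_config <- function(cfg, dir, stage) {
  out <- cfg
  out$cohort$spec <- NULL  # the synthetic args are already in the config
  jsonlite::write_json(out, file.path(dir, paste0(stage, "_config.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}

#' Stage 1: simulate a synthetic cohort to disk
#'
#' Generates the configured synthetic cohort and writes its NIfTI volumes
#' plus manifest (including per-subject tau, failure mode and true Dice)
#' under `output_dir/cohort`. Re-running the same config reproduces the
#' manifest byte-identically.
#'
#' @param config a `uq_config` (or path to one).
#' @return path to the written manifest.
#' @export
run_simulate <- function(config) {
  cfg <- if (inherits(config, "uq_config")) config else load_config(config)
  if (is.null(cfg$cohort$spec))
    config_error("run_simulate needs a synthetic cohort spec")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(cfg$cohort$spec, compute_dice = TRUE)
  path <- write_cohort(cohort, file.path(cfg$output_dir, "cohort"))
  write_resolved_config(cfg, cfg$output_dir, "simulate")
  message(sprintf("simulate: wrote %d subjects to %s",
                  n_subjects(cohort), dirname(path)))
  path
}

#' Stage 2: voxel-level evaluation (calibration + error localization)
#'
#' Per-subject ECE/ACE/calibration class within the brain mask, pooled
#' dataset-level reliability diagrams, the U-E threshold sweep on the
#' validation split, and per-test-subject U-E and AUC-PR at the selected
#' thresholds. Writes `calibration.csv`, `reliability_<region>.json`,
#' `thresholds.json`, `localization.csv`.
#'
#' @param config a `uq_config` (or path).
#' @param cohort optionally, an already-resolved cohort.
#' @return list with the calibration table, threshold selections and
#'   localization table (invisibly also written to disk).
#' @export
run_evaluate_voxel <- function(config, cohort = NULL) {
  cfg <- if (inherits(config, "uq_config")) config else load_config(config)
  if (is.null(cohort)) cohort <- resolve_cohort(cfg)
  regions <- cfg$regions %||% cohort_regions(cohort)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  cal <- cohort_calibration(cohort, regions, M = cfg$bins,
                            tolerance = cfg$calibration_tolerance)
  write.csv(cal$table, file.path(cfg$output_dir, "calibration.csv"),
            row.names = FALSE)

  for (r in regions) {
    dia <- dataset_reliability(cohort, r, M = cfg$bins)
    jsonlite::write_json(
      list(region = r, scope = dia$scope, bin_edges = dia$bin_edges,
           confidences = dia$confidences, accuracies = dia$accuracies,
           counts = dia$counts, n = dia$n,
           ece = expected_calibration_error(dia)),
      file.path(cfg$output_dir, paste0("reliability_", r, ".json")),
      auto_unbox = TRUE, digits = NA, na = "null")
  }

  thresholds <- list()
  has_val <- any(cohort$manifest$split == "validation")
  if (has_val) {
    for (r in regions) thresholds[[r]] <- select_threshold(cohort, r)
    jsonlite::write_json(
      lapply(thresholds, function(t)
        list(method_id = t$method_id, region = t$region,
             threshold = t$threshold,
             sweep = as.list(stats::setNames(t$sweep$mean_ue,
                                             sprintf("%.2f", t$sweep$threshold))))),
      file.path(cfg$output_dir, "thresholds.json"),
      auto_unbox = TRUE, digits = NA)
  }

  loc_rows <- list()
  test_idx <- which(cohort$manifest$split == "test")
  if (has_val && length(test_idx) > 0) {
    for (i in test_idx) {
      s <- cohort_subject(cohort, i)
      for (r in regions) {
        ok <- !is.null(s$prob_maps[[r]]) || !is.null(s$uncertainty_maps[[r]])
        if (!ok) {
          warning("subject ", s$subject_id, " lacks maps for ", r,
                  "; skipped")
          next
        }
        q <- subject_uncertainty(s, r)
        E <- error_map(s$pred_labels[[r]], s$gt_labels[[r]])
        ue <- uncertainty_error_overlap(q, E, thresholds[[r]]$threshold,
                                        s$brain_mask)
        pr <- suppressWarnings(
          uncertainty_error_auc_pr(q, E, s$brain_mask))
        loc_rows[[length(loc_rows) + 1L]] <- tibble::tibble(
          subject_id = s$subject_id, region = r,
          threshold = thresholds[[r]]$threshold, ue = ue, auc_pr = pr)
      }
    }
  }
  loc <- dplyr::bind_rows(loc_rows)
  write.csv(loc, file.path(cfg$output_dir, "localization.csv"),
            row.names = FALSE)
  write_resolved_config(cfg, cfg$output_dir, "evaluate_voxel")
  message(sprintf("evaluate-voxel: %d subjects, %d regions",
                  n_subjects(cohort), length(regions)))
  invisible(list(calibration = cal, thresholds = thresholds,
                 localization = loc))
}

#' Stage 3: subject-level aggregation and failure detection
#'
#' Extracts the configured aggregation families for every subject, trains
#' a Dice regressor per (family, region) on the training split (for the
#' prior-knowledge and automatic families), scores the test split, and
#' evaluates failure detection (Spearman rho, AUC-ROC, Youden accuracy)
#' against the config-supplied per-region Dice cutoffs. Writes
#' `features.csv`, `summary.csv`, `roc_<family>_<region>.csv` and
#' `regressor_<family>_<region>.json`.
#'
#' @param config a `uq_config` (or path).
#' @param cohort optionally, an already-resolved cohort.
#' @param thresholds named list region -> `uq_threshold`; when NULL they
#'   are re-selected on the validation split.
#' @return list with `features`, `summary` (tibble), `results`
#'   (list of `uq_failure_result`), `regressors`.
#' @export
run_detect_failures <- function(config, cohort = NULL, thresholds = NULL) {
  cfg <- if (inherits(config, "uq_config")) config else load_config(config)
  if (is.null(cfg$dice_cutoffs))
    config_error("detect-failures requires dice_cutoffs per region")
  if (is.null(cohort)) cohort <- resolve_cohort(cfg)
  regions <- cfg$regions %||% cohort_regions(cohort)
  missing_cut <- setdiff(regions, names(cfg$dice_cutoffs))
  if (length(missing_cut) > 0)
    config_error(paste("missing dice_cutoffs for:",
                       paste(missing_cut, collapse = ", ")))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(thresholds) && "automatic" %in% cfg$families) {
    thresholds <- list()
    for (r in regions) thresholds[[r]] <- select_threshold(cohort, r)
  }
  feats <- cohort_features(cohort, regions, thresholds,
                           families = cfg$families)
  write.csv(feats, file.path(cfg$output_dir, "features.csv"),
            row.names = FALSE)

  results <- list(); regressors <- list(); summaries <- list()
  for (fam in cfg$families) {
    for (r in regions) {
      fr <- dplyr::filter(feats, .data$family == fam, .data$region == r)
      train <- dplyr::filter(fr, .data$split == "train")
      test <- dplyr::filter(fr, .data$split == "test")
      if (nrow(test) < 2) {
        warning("fewer than 2 test subjects for ", fam, "/", r, "; skipped")
        next
      }
      if (fam == "mean") {
        scores <- test$neg_mean_uncertainty
      } else {
        reg <- fit_dice_regressor(train, ntree = cfg$regressor$ntree,
                                  seed = cfg$regressor$seed)
        regressors[[paste(fam, r, sep = "_")]] <- reg
        jsonlite::write_json(
          list(family = fam, region = r, seed = reg$seed,
               ntree = reg$ntree, oob_rsq = reg$oob_rsq,
               feature_names = reg$feature_names,
               importances = as.list(reg$importances)),
          file.path(cfg$output_dir,
                    paste0("regressor_", fam, "_", r, ".json")),
          auto_unbox = TRUE, digits = NA)
        scores <- predict(reg, test)
      }
      res <- evaluate_failure_detection(
        scores, test$true_dice, cfg$dice_cutoffs[[r]],
        region = r, family = fam)
      results[[paste(fam, r, sep = "_")]] <- res
      summaries[[length(summaries) + 1L]] <- glance(res)
      if (!is.null(res$roc))
        write.csv(res$roc,
                  file.path(cfg$output_dir,
                            paste0("roc_", fam, "_", r, ".csv")),
                  row.names = FALSE)
    }
  }
  summary <- dplyr::bind_rows(summaries)
  write.csv(summary, file.path(cfg$output_dir, "summary.csv"),
            row.names = FALSE)
  write_resolved_config(cfg, cfg$output_dir, "detect_failures")
  message(sprintf("detect-failures: %d family x region results",
                  nrow(summary)))
  invisible(list(features = feats, summary = summary, results = results,
                 regressors = regressors))
}
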