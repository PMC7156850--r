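# Synthetic cohort generator: determinism, hierarchy, calibration
# guarantees, failure modes.

test_that("cohort specs are validated before any computation", {
  expect_error(small_spec(failure_mix = c(clean = 0.5, remote_blob = 0.2)),
               "sum to 1")
  expect_error(small_spec(failure_mix = c(weird = 1)), "unknown failure")
  expect_error(small_spec(tau = -1), "tau must be")
  expect_error(small_spec(split_fractions = c(train = 1, validation = 0.5,
                                              test = -0.5)), "sum to 1")
  expect_error(cohort_spec(dims = c(32, 32, 24), wt_radius_range = c(12, 20)),
               "infeasible nesting")
})

test_that("phantoms are deterministic, nested and respect the brain mask", {
  spec <- small_spec(seed = 5)
  p1 <- generate_phantom(spec, 123L)
  p2 <- generate_phantom(spec, 123L)
  expect_identical(p1$gt, p2$gt)
  expect_identical(p1$brain_mask, p2$brain_mask)
  for (s in c(1L, 77L, 1234L)) {
    ph <- generate_phantom(spec, s)
    expect_false(any(ph$gt$ET & !ph$gt$TC))
    expect_false(any(ph$gt$TC & !ph$gt$WT))
    expect_false(any(ph$gt$WT & !ph$brain_mask))
    expect_gt(sum(ph$gt$ET), 0)
  }
})

test_that("zero deformation gives exact nested spheres", {
  spec <- small_spec(deform_amplitude = 0, brain_scale_range = c(1, 1))
  ph <- generate_phantom(spec, 42L)
  co <- uqseg:::coord_arrays(spec$dims, spec$spacing)
  dist <- sqrt((co$x - ph$center[1])^2 + (co$y - ph$center[2])^2 +
                 (co$z - ph$center[3])^2)
  expect_identical(ph$gt$WT, (dist <= ph$wt_radius) & ph$brain_mask)
  expect_identical(ph$gt$TC,
                   (dist <= spec$tc_frac * ph$wt_radius) & ph$brain_mask)
})

test_that("the noiseless sharp-boundary limit reproduces the ground truth", {
  spec <- small_spec(boundary_sigma_mm = 0.2, noise_amplitude = 0,
                     mode = "morphology")
  ph <- generate_phantom(spec, 7L)
  sim <- simulate_predictor(ph, spec, 8L, tau = 1)
  expect_equal(dice_coefficient(sim$pred$WT, sim$gt$WT), 1)
  expect_equal(dice_coefficient(sim$pred$ET, sim$gt$ET), 1)
})

test_that("predictions are invariant to temperature; tau <= 0 is rejected", {
  spec <- small_spec()
  ph <- generate_phantom(spec, 3L)
  s1 <- simulate_predictor(ph, spec, 4L, tau = 1)
  s2 <- simulate_predictor(ph, spec, 4L, tau = 0.5)
  s3 <- simulate_predictor(ph, spec, 4L, tau = 2)
  expect_identical(s1$pred, s2$pred)
  expect_identical(s1$pred, s3$pred)
  expect_error(simulate_predictor(ph, spec, 4L, tau = 0), "tau must be")
})

test_that("calibration mode redraws nested ground truth from the latent field", {
  spec <- small_spec(mode = "calibration")
  ph <- generate_phantom(spec, 11L)
  sim <- simulate_predictor(ph, spec, 12L, tau = 1)
  # shared-uniform redraw keeps the hierarchy
  expect_false(any(sim$gt$ET & !sim$gt$TC))
  expect_false(any(sim$gt$TC & !sim$gt$WT))
  # redrawn gt differs from the deterministic phantom in the transition zone
  expect_gt(sum(xor(sim$gt$WT, ph$gt$WT)), 0)
  # and stays inside the brain
  expect_false(any(sim$gt$WT & !sim$brain_mask))
})

test_that("calibration-mode subjects are nearly perfectly calibrated at tau 1", {
  spec <- calibration_study_spec(n_subjects = 1, seed = 31)
  s <- cohort_subject(generate_cohort(spec, compute_dice = FALSE), 1)
  dia <- reliability_diagram(subject_confidence(s, "WT"), s$gt_labels$WT,
                             s$brain_mask)
  expect_lt(expected_calibration_error(dia), 0.01)
  occ <- which(dia$counts > 0)
  expect_true(all(abs(dia$confidences[occ] - dia$accuracies[occ]) < 0.05))
})

test_that("remote blobs drop Dice while barely moving mean uncertainty", {
  spec <- small_spec(failure_mix = c(remote_blob = 1), seed = 21,
                     blob_prob = 0.99)
  ph <- generate_phantom(spec, 5L)
  sim <- simulate_predictor(ph, spec, 6L, tau = 1)
  clean_dice <- dice_coefficient(sim$pred$WT, sim$gt$WT)
  clean_mean <- mean(normalized_entropy(sim$prob$WT)$values[ph$brain_mask])
  corr <- inject_failure(sim, "remote_blob", spec, 9L)
  corr_dice <- dice_coefficient(corr$pred$WT, corr$gt$WT)
  corr_mean <- mean(normalized_entropy(corr$prob$WT)$values[ph$brain_mask])
  expect_lt(corr_dice, clean_dice - 0.03)
  expect_lt(abs(corr_mean - clean_mean), 0.02)
  expect_equal(corr$failure$mode, "remote_blob")
  expect_gte(corr$failure$n_blobs, 1)
  # uncertainty-only patches leave the prediction unchanged where they act
  expect_true(all(corr$prob$WT[corr$prob$WT < 0.5] <= 0.5))
})

test_that("boundary jitter with zero amplitude leaves the subject unchanged", {
  spec <- small_spec(jitter_amplitude = 0)
  ph <- generate_phantom(spec, 13L)
  sim <- simulate_predictor(ph, spec, 14L, tau = 1)
  j <- inject_failure(sim, "boundary_jitter", spec, 15L)
  expect_identical(j$prob, sim$prob)
  expect_identical(j$pred, sim$pred)
})

test_that("missing half the core yields Dice near 2/3", {
  spec <- small_spec(boundary_sigma_mm = 0.2, noise_amplitude = 0,
                     deform_amplitude = 0)
  ph <- generate_phantom(spec, 17L)
  sim <- simulate_predictor(ph, spec, 18L, tau = 1)
  m <- inject_failure(sim, "missed_core", spec, 19L)
  d <- dice_coefficient(m$pred$TC, m$gt$TC)
  expect_equal(d, 2 / 3, tolerance = 0.06)
})

test_that("cohorts are pure functions of spec and master seed", {
  spec <- small_spec(n_subjects = 5, seed = 77,
                     failure_mix = c(clean = 0.6, remote_blob = 0.4),
                     split_fractions = c(train = 0.4, validation = 0.2,
                                         test = 0.4))
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  s1 <- cohort_subject(c1, 3); s2 <- cohort_subject(c2, 3)
  expect_identical(s1$prob_maps$WT, s2$prob_maps$WT)
  expect_identical(s1$gt_labels$WT, s2$gt_labels$WT)
  # manifest CSV serialization is byte-identical
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(c1$manifest, f1, row.names = FALSE)
  write.csv(c2$manifest, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # split apportionment follows the configured fractions
  expect_equal(unname(table(c1$manifest$split)[c("train", "validation",
                                                 "test")]),
               c(2L, 1L, 2L), ignore_attr = TRUE)
  expect_equal(sum(c1$manifest$failure_mode == "remote_blob"), 2)
})

test_that("an all-clean cohort concentrates Dice near 1", {
  # mild boundary noise relative to the (small) phantom size
  spec <- small_spec(n_subjects = 6, seed = 23, noise_amplitude = 0.2,
                     boundary_sigma_mm = 1.0)
  coh <- generate_cohort(spec)
  expect_true(all(coh$manifest$true_dice_WT > 0.85))
  expect_true(median(coh$manifest$true_dice_WT) > 0.9)
})

test_that("native-uncertainty mode ships uncertainty maps instead of probabilities", {
  spec <- small_spec(n_subjects = 2, seed = 29, native_uncertainty = TRUE)
  coh <- generate_cohort(spec, compute_dice = FALSE)
  s <- cohort_subject(coh, 1)
  expect_null(s$prob_maps)
  expect_s3_class(s$uncertainty_maps$WT, "uq_uncertainty")
  expect_equal(s$uncertainty_maps$WT$provenance, "native")
  # confidence accessor falls back to the translation
  conf <- subject_confidence(s, "WT")
  expect_true(all(conf[s$pred_labels$WT] >= 0.5))
})
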