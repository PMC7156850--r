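# Error maps, U-E overlap, threshold selection, AUC-PR.

test_that("error map is the XOR of prediction and truth", {
  d <- c(3, 3, 1)
  gt <- make_box(d, c(1, 1, 1), c(2, 3, 1))
  expect_equal(error_map(gt, gt), array(FALSE, d))
  expect_equal(error_map(!gt, gt), array(TRUE, d))
  # 2 FP + 3 FN on a 3x3 grid
  pred <- array(FALSE, d); pred[3, 1:2, 1] <- TRUE       # 2 FP
  gt2 <- array(FALSE, d); gt2[1, 1:3, 1] <- TRUE         # 3 FN
  expect_equal(sum(error_map(pred, gt2)), 5)
  expect_error(error_map(array(0.5, d), gt), "binary")
})

test_that("U-E overlap matches the Dice formula and its conventions", {
  d <- c(4, 4, 1)
  E <- make_box(d, c(1, 1, 1), c(2, 2, 1))
  q <- array(0, d); q[E] <- 0.9
  expect_equal(uncertainty_error_overlap(q, E, 0.5), 1)
  q2 <- array(0, d); q2[3:4, 3:4, 1] <- 0.9     # disjoint from E
  expect_equal(uncertainty_error_overlap(q2, E, 0.5), 0)
  # |U| = 4, |E| = 4, |U ∩ E| = 2
  q3 <- array(0, d); q3[1:2, 2:3, 1] <- 0.9
  E3 <- make_box(d, c(1, 1, 1), c(2, 2, 1))
  expect_equal(uncertainty_error_overlap(q3, E3, 0.5), 0.5)
  # conventions: both empty -> 1; one empty -> 0
  expect_equal(uncertainty_error_overlap(array(0, d), array(FALSE, d), 0.5), 1)
  expect_equal(uncertainty_error_overlap(array(0, d), E, 0.5), 0)
  expect_equal(uncertainty_error_overlap(q, array(FALSE, d), 0.5), 0)
  # closed threshold: q = 0.95 attains t = 0.95
  q4 <- array(0, d); q4[E] <- 0.95
  expect_equal(uncertainty_error_overlap(q4, E, 0.95), 1)
})

test_that("U-E agrees with the brute-force oracle on random instances", {
  set.seed(17)
  for (k in 1:40) {
    d <- c(sample(3:8, 1), sample(3:8, 1), sample(2:4, 1))
    q <- array(round(runif(prod(d)), 2), d)
    E <- array(runif(prod(d)) < 0.3, d)
    thr <- sample(ue_threshold_grid(), 1)
    expect_equal(uncertainty_error_overlap(q, E, thr), ue_oracle(q, E, thr))
  }
})

test_that("U-E ignores voxels outside U and E", {
  d <- c(5, 5, 2)
  set.seed(4)
  q <- array(runif(prod(d)), d)
  E <- array(runif(prod(d)) < 0.2, d)
  base <- uncertainty_error_overlap(q, E, 0.6)
  q2 <- q
  tn <- q < 0.6 & !E
  q2[tn] <- q2[tn] / 2   # perturb true-negative uncertainty below threshold
  expect_equal(uncertainty_error_overlap(q2, E, 0.6), base)
})

test_that("the sweep grid is exactly 0.05..0.95 by 0.05", {
  expect_equal(ue_threshold_grid(), seq(0.05, 0.95, by = 0.05))
  expect_length(ue_threshold_grid(), 19)
})

test_that("threshold selection takes the argmax with low-threshold ties", {
  # q = 0.9 exactly on E: every threshold in (0, 0.9] scores 1 -> pick 0.05
  spec <- small_spec(n_subjects = 6, seed = 2,
                     split_fractions = c(train = 0.2, validation = 0.4,
                                         test = 0.4))
  coh <- generate_cohort(spec, compute_dice = FALSE)
  # build a manual cohort-like threshold selection via a fabricated subject:
  d <- c(6, 6, 2)
  E <- make_box(d, c(2, 2, 1), c(4, 4, 2))
  q <- array(0, d); q[E] <- 0.9
  sweep <- sapply(ue_threshold_grid(), function(t)
    uncertainty_error_overlap(q, E, t))
  expect_equal(unname(sweep[1:18]), rep(1, 18))  # all t <= 0.9 perfect
  expect_equal(unname(sweep[19]), 0)
  expect_equal(ue_threshold_grid()[which.max(sweep)], 0.05)
  # cohort-level: sweep table equals brute recomputation, threshold attains max
  sel <- select_threshold(coh, "WT")
  expect_s3_class(sel, "uq_threshold")
  val_idx <- which(coh$manifest$split == "validation")
  brute <- sapply(ue_threshold_grid(), function(t) {
    mean(sapply(val_idx, function(i) {
      s <- cohort_subject(coh, i)
      q <- subject_uncertainty(s, "WT")
      E <- error_map(s$pred_labels$WT, s$gt_labels$WT)
      uncertainty_error_overlap(q$values, E, t, s$brain_mask)
    }))
  })
  expect_equal(sel$sweep$mean_ue, unname(brute), tolerance = 1e-12)
  expect_equal(sel$threshold,
               ue_threshold_grid()[which.max(brute)])
  expect_equal(max(sel$sweep$mean_ue), sel$sweep$mean_ue[
    which(sel$sweep$threshold == sel$threshold)])
  expect_error(select_threshold(coh, "WT", split = "no_such_split"),
               "empty validation")
})

test_that("AUC-PR: perfect ranking, random baseline, hand-enumerated toy", {
  d <- c(6, 1, 1)
  E <- array(c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE), d)
  q_perfect <- array(as.numeric(E), d)
  expect_equal(uncertainty_error_auc_pr(q_perfect, E), 1)
  # hand-enumerable 6-voxel case vs exhaustive threshold-scan oracle
  q <- array(c(0.9, 0.8, 0.7, 0.6, 0.7, 0.1), d)
  expect_equal(uncertainty_error_auc_pr(q, E),
               aucpr_oracle(as.vector(q), as.integer(E)))
  set.seed(23)
  for (k in 1:20) {
    n <- sample(10:200, 1)
    qq <- array(round(runif(n), 2), c(n, 1, 1))
    EE <- array(runif(n) < 0.4, c(n, 1, 1))
    if (!any(EE)) EE[1] <- TRUE
    expect_equal(uncertainty_error_auc_pr(qq, EE),
                 aucpr_oracle(as.vector(qq), as.integer(EE)),
                 tolerance = 1e-12)
  }
  # scores independent of errors -> roughly the prevalence
  set.seed(29)
  n <- 4e4
  qq <- array(runif(n), c(n, 1, 1))
  EE <- array(runif(n) < 0.15, c(n, 1, 1))
  expect_equal(uncertainty_error_auc_pr(qq, EE), 0.15, tolerance = 0.02)
  # empty error map is undefined
  expect_warning(r <- uncertainty_error_auc_pr(qq, array(FALSE, c(n, 1, 1))),
                 "undefined")
  expect_true(is.na(r))
})

test_that("AUC-PR is invariant under strictly increasing transforms", {
  set.seed(31)
  n <- 500
  q <- array(runif(n), c(n, 1, 1))
  E <- array(runif(n) < 0.3, c(n, 1, 1))
  a1 <- uncertainty_error_auc_pr(q, E)
  a2 <- uncertainty_error_auc_pr(array(q^3, dim(q)), E)
  a3 <- uncertainty_error_auc_pr(array(plogis(5 * q), dim(q)), E)
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("U-E is piecewise constant in the threshold", {
  set.seed(37)
  q <- array(sample(c(0.2, 0.5, 0.8), 27, replace = TRUE), c(3, 3, 3))
  E <- array(runif(27) < 0.4, c(3, 3, 3))
  grid <- seq(0.01, 0.99, by = 0.01)
  vals <- sapply(grid, function(t) uncertainty_error_overlap(q, E, t))
  # at most |distinct q| + 1 = 4 distinct pieces
  expect_lte(length(unique(vals)), 4)
})
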