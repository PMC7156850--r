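# Dice, quality binarization, Spearman, ROC/AUC, Youden accuracy.

test_that("Dice coefficient matches hand evaluation and conventions", {
  d <- c(4, 4, 1)
  a <- make_box(d, c(1, 1, 1), c(2, 3, 1))
  expect_equal(dice_coefficient(a, a), 1)
  b <- make_box(d, c(4, 1, 1), c(4, 4, 1))
  expect_equal(dice_coefficient(a, b), 0)
  # |P| = 6, |G| = 4, |P ∩ G| = 3 -> 0.6
  P <- array(FALSE, d); P[1:3, 1:2, 1] <- TRUE
  G <- array(FALSE, d); G[2:3, 1:2, 1] <- TRUE; G[2, 1, 1] <- TRUE
  G[3, 2, 1] <- FALSE; G[4, 4, 1] <- TRUE
  expect_equal(sum(P), 6); expect_equal(sum(G), 4)
  expect_equal(sum(P & G), 3)
  expect_equal(dice_coefficient(P, G), 0.6)
  empty <- array(FALSE, d)
  expect_equal(dice_coefficient(empty, empty), 1)
  expect_equal(dice_coefficient(a, empty), 0)
  # random instances vs oracle
  set.seed(41)
  for (k in 1:20) {
    x <- array(runif(48) < 0.4, d <- c(4, 4, 3))
    y <- array(runif(48) < 0.4, d)
    expect_equal(dice_coefficient(x, y), dice_oracle(x, y))
  }
})

test_that("quality binarization uses dice < cutoff with failure positive", {
  expect_equal(binarize_quality(c(0.9, 0.7, 0.85), 0.85),
               c(FALSE, TRUE, FALSE))  # dice == cutoff is successful
  expect_error(binarize_quality(0.5, 0), "\\(0, 1\\)")
  expect_error(binarize_quality(0.5, 1), "\\(0, 1\\)")
  set.seed(43)
  dice <- c(runif(10, 0.2, 0.5), runif(10, 0.9, 1))
  expect_equal(binarize_quality(dice, 0.75), dice < 0.75)
})

test_that("Spearman correlation: monotone extremes, ties, constant input", {
  x <- 1:10
  expect_equal(spearman_correlation(x, x^3), 1)
  expect_equal(spearman_correlation(x, exp(x / 3)), 1)
  expect_equal(spearman_correlation(x, -x - 100), -1)
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
  expect_warning(r <- spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  # 5 hand-ranked pairs vs rank-then-Pearson oracle
  set.seed(47)
  for (k in 1:15) {
    a <- sample(20, 8, replace = TRUE)  # ties likely
    b <- sample(20, 8, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_correlation(a, b), spearman_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("AUC-ROC matches the pairwise-comparison definition", {
  # perfect separator: scores = 1 - label
  lab <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(roc_auc(1 - as.numeric(lab), lab)$auc, 1)
  # 6 hand-listed pairs vs exhaustive O(n^2) oracle
  sc <- c(0.9, 0.8, 0.8, 0.4, 0.3, 0.2)
  lb <- c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE)
  expect_equal(roc_auc(sc, lb)$auc, auc_pair_oracle(sc, lb))
  set.seed(53)
  for (k in 1:20) {
    n <- sample(6:40, 1)
    sc <- round(runif(n), 1)
    lb <- runif(n) < 0.4
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb)$auc, auc_pair_oracle(sc, lb),
                 tolerance = 1e-12)
  }
  # single class undefined
  expect_warning(r <- roc_auc(1:5, rep(TRUE, 5)), "single-class")
  expect_true(is.na(r$auc))
})

test_that("label-independent scores give AUC near 0.5; sign flip mirrors AUC", {
  set.seed(59)
  n <- 2000
  sc <- runif(n); lb <- runif(n) < 0.3
  a <- roc_auc(sc, lb)$auc
  expect_equal(a, 0.5, tolerance = 0.03)
  # strictly increasing transform leaves AUC unchanged; negation flips it
  a2 <- roc_auc(qlogis(pmin(pmax(sc, 1e-6), 1 - 1e-6)), lb)$auc
  expect_equal(a, a2)
  a3 <- roc_auc(-sc, lb)$auc
  expect_equal(a3, 1 - a, tolerance = 1e-12)
})

test_that("Youden point maximizes J and accuracy matches its confusion matrix", {
  # direct formula: sens 0.8, spec 0.7 -> J = 0.5
  roc <- tibble::tibble(threshold = 0.5, fpr = 0.3, tpr = 0.8)
  y <- youden_accuracy(roc, c(0.4, 0.6), c(TRUE, FALSE))
  expect_equal(y$youden_j, 0.5)
  # 8-subject cohort vs exhaustive threshold scan
  set.seed(61)
  for (k in 1:15) {
    sc <- round(runif(8), 1)
    lb <- runif(8) < 0.5
    if (length(unique(lb)) < 2) next
    r <- roc_auc(sc, lb)
    y <- youden_accuracy(r$roc, sc, lb)
    o <- youden_scan_oracle(sc, lb)
    expect_equal(y$youden_j, o$j, tolerance = 1e-9)
    # accuracy consistent with the confusion matrix at the chosen threshold
    pf <- sc < y$threshold
    expect_equal(y$accuracy, mean(pf == lb))
    expect_gte(y$accuracy, 0); expect_lte(y$accuracy, 1)
  }
})

test_that("evaluate_failure_detection bundles metrics coherently", {
  set.seed(67)
  dice <- c(runif(12, 0.9, 1), runif(6, 0.3, 0.7))
  scores <- dice + rnorm(18, 0, 0.05)
  res <- evaluate_failure_detection(scores, dice, 0.85, "WT", "mean")
  expect_s3_class(res, "uq_failure_result")
  g <- glance(res)
  expect_equal(g$n, 18)
  expect_equal(g$n_failed, sum(dice < 0.85))
  expect_gt(g$auc_roc, 0.9)
  expect_gt(g$spearman_rho, 0.8)
  td <- tidy(res)
  expect_equal(nrow(td), 18)
  # perfect separator: interior-threshold accuracy 1
  res2 <- evaluate_failure_detection(dice, dice, 0.85)
  expect_equal(res2$auc_roc, 1)
  expect_equal(res2$youden_accuracy, 1)
  # single-class cohort reported as undefined
  res3 <- suppressWarnings(
    evaluate_failure_detection(runif(5), runif(5, 0.9, 1), 0.5))
  expect_true(is.na(res3$auc_roc))
  expect_true(is.na(res3$youden_accuracy))
})
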