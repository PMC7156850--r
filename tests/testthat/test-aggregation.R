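# Subject-level aggregation: mean, prior-knowledge weightings, regressor,
# rank accumulation.

test_that("mean aggregation is minus the masked mean", {
  d <- c(4, 4, 2)
  mask <- array(TRUE, d)
  expect_equal(mean_aggregate(array(0, d), mask), 0)
  expect_equal(mean_aggregate(array(1, d), mask), -1)
  q <- array(0, d); m2 <- make_box(d, c(1, 1, 1), c(2, 2, 2))
  q[m2] <- 0.25
  expect_equal(mean_aggregate(q, m2), -0.25)
  expect_error(mean_aggregate(q, array(FALSE, d)), "empty mask")
  # invariance to voxels outside the mask; linearity in q
  set.seed(73)
  q <- array(runif(prod(d)), d)
  base <- mean_aggregate(q, m2)
  q_out <- q; q_out[!m2] <- runif(sum(!m2))
  expect_equal(mean_aggregate(q_out, m2), base)
  expect_equal(mean_aggregate(array(2 * q, d) / 2, m2), base)
})

test_that("boundary band is the surface plus one shell in and out", {
  d <- c(11, 11, 11)
  cube <- make_box(d, c(4, 4, 4), c(8, 8, 8))    # 5^3 cube
  band <- boundary_band(cube)
  # interior 3^3 core excluded, surface + inner shell inside, outer shell out
  core <- make_box(d, c(5, 5, 5), c(7, 7, 7))
  inner_shell <- cube & !core
  expect_true(all(band[inner_shell]))
  expect_false(any(band[make_box(d, c(6, 6, 6), c(6, 6, 6))]))
  # outer shell: face neighbours of the surface
  expect_true(band[3, 6, 6] && band[9, 6, 6] && band[6, 3, 6])
  expect_false(band[2, 6, 6])
  # single voxel -> itself plus its 6 face neighbours
  sv <- array(FALSE, d); sv[6, 6, 6] <- TRUE
  b1 <- boundary_band(sv)
  expect_equal(sum(b1), 7)
  expect_true(b1[6, 6, 6] && b1[5, 6, 6] && b1[6, 6, 7])
  expect_equal(boundary_band(array(FALSE, d)), array(FALSE, d))
})

test_that("prior-knowledge features follow their closed forms", {
  d <- c(12, 12, 10)
  mask <- array(TRUE, d)
  pred <- make_ball(d, 3, c(6, 6, 5))
  band <- boundary_band(pred)
  # q supported only on the band -> all boundary-masked reducers are 0
  q_band <- array(0, d); q_band[band] <- 0.7
  f <- prior_knowledge_features(q_band, pred, mask)
  expect_equal(unname(f["boundary_masked_mean"]), 0)
  expect_equal(unname(f["boundary_masked_sum"]), 0)
  expect_equal(unname(f["boundary_masked_logsum"]), 0)
  # constant q = c: volume-normalized sum = c |mask| / V
  qc <- array(0.2, d)
  f2 <- prior_knowledge_features(qc, pred, mask)
  expect_equal(unname(f2["volume_normalized_sum"]),
               0.2 * sum(mask) / sum(pred))
  expect_equal(unname(f2["volume_normalized_logsum"]),
               log1p(0.2 * sum(mask) / sum(pred)))
  # distance weighting: doubling a remote blob's distance doubles its term
  q1 <- array(0, d); q1[11, 6, 5] <- 1   # 5 voxels from the pred boundary
  q2 <- array(0, d); q2[6, 6, 9] <- 1
  f_near <- prior_knowledge_features(q1, pred, mask)
  dists <- boundary_distance(pred)
  expect_equal(unname(f_near["distance_weighted_masked_sum"]),
               dists[11, 6, 5])
  # the feature is exactly q-weighted distance, so scaling distance scales it
  expect_equal(unname(prior_knowledge_features(q2, pred, mask)["distance_weighted_masked_sum"]),
               dists[6, 6, 9])
  # empty prediction: distance/volume features missing
  f3 <- prior_knowledge_features(qc, array(FALSE, d), mask)
  expect_true(is.na(f3["distance_weighted_masked_mean"]))
  expect_true(is.na(f3["volume_normalized_sum"]))
  expect_false(is.na(f3["boundary_masked_mean"]))
})

test_that("boundary-masked features ignore arbitrary band values", {
  d <- c(12, 12, 10)
  pred <- make_ball(d, 3, c(6, 6, 5))
  mask <- array(TRUE, d)
  set.seed(79)
  q <- array(runif(prod(d)), d)
  band <- boundary_band(pred)
  f1 <- prior_knowledge_features(q, pred, mask)
  q2 <- q; q2[band] <- runif(sum(band))
  f2 <- prior_knowledge_features(q2, pred, mask)
  expect_equal(f1[grep("boundary_masked", names(f1))],
               f2[grep("boundary_masked", names(f2))])
})

test_that("the Dice regressor recovers signal, fails negative controls, and is deterministic", {
  set.seed(83)
  n <- 200
  feats <- tibble::tibble(
    a = runif(n), b = runif(n), c = runif(n),
    true_dice = NA_real_)
  feats$true_dice <- feats$a          # target equals one feature
  tr <- feats[1:120, ]; te <- feats[121:200, ]
  fit <- fit_dice_regressor(tr, seed = 5)
  p <- predict(fit, te)
  expect_gt(cor(p, te$true_dice, method = "spearman"), 0.95)
  expect_true(all(p >= 0 & p <= 1))
  # permuted target -> no held-out correlation
  set.seed(84)
  tr_perm <- tr; tr_perm$true_dice <- sample(tr$true_dice)
  fit0 <- fit_dice_regressor(tr_perm, seed = 5)
  expect_lt(abs(cor(predict(fit0, te), te$true_dice, method = "spearman")),
            0.25)
  # same seed, same data -> identical predictions
  fit2 <- fit_dice_regressor(tr, seed = 5)
  expect_identical(predict(fit2, te), p)
  # guards
  expect_error(fit_dice_regressor(tr[1:5, ]), "at least 10")
  tr_const <- tr; tr_const$true_dice <- 0.5
  expect_error(fit_dice_regressor(tr_const), "constant Dice")
  expect_error(predict(fit, te[, "b", drop = FALSE]), "mismatch")
})

test_that("missing features are imputed with indicator columns", {
  set.seed(87)
  n <- 40
  feats <- tibble::tibble(a = runif(n), b = runif(n))
  feats$b[1:5] <- NA
  dice <- feats$a + 0.1 * runif(n)
  fit <- fit_dice_regressor(feats, dice = pmin(dice, 1), seed = 3)
  expect_true("miss_b" %in% fit$feature_names)
  newd <- tibble::tibble(a = runif(4), b = c(NA, 0.5, NA, 0.2))
  expect_length(predict(fit, newd), 4)
})

test_that("rank accumulation sums per-model ranks with alphabetical ties", {
  mk <- function(imp) structure(list(importances = imp), class = "uq_dice_regressor")
  m1 <- mk(c(a = 3, b = 2, c = 1))
  r1 <- rank_accumulate_importance(list(m1))
  expect_equal(r1$feature, c("a", "b", "c"))
  # unanimous winner ranks first overall
  m2 <- mk(c(a = 10, b = 1, c = 5))
  m3 <- mk(c(a = 9, b = 8, c = 2))
  r <- rank_accumulate_importance(list(m1, m2, m3))
  expect_equal(r$feature[1], "a")
  # hand-summed ranks: a: 1+1+1=3, b: 2+3+2=7, c: 3+2+3=8
  expect_equal(r$total_rank, c(3, 7, 8))
  # alphabetical tie-break
  m4 <- mk(c(a = 1, b = 2, c = 3)); m5 <- mk(c(a = 3, b = 2, c = 1))
  r2 <- rank_accumulate_importance(list(m4, m5))
  expect_equal(r2$total_rank, rep(4, 3))
  expect_equal(r2$feature, c("a", "b", "c"))
  expect_error(rank_accumulate_importance(list(m1, mk(c(x = 1, y = 2, z = 3)))),
               "mismatched")
})
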