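# Reliability diagrams, ECE/ACE, subject classification, cohort summaries.

toy_diagram <- function(conf, gt, M = 10, mask = NULL) {
  d <- c(length(conf), 1, 1)
  reliability_diagram(array(conf, d), array(gt, d),
                      if (is.null(mask)) NULL else array(mask, d), M = M)
}

test_that("reliability diagram bins a hand-checked toy case", {
  dia <- toy_diagram(rep(0.8, 4), c(1, 1, 1, 0))
  occ <- which(dia$counts > 0)
  expect_equal(length(occ), 1)
  expect_equal(dia$confidences[occ], 0.8)
  expect_equal(dia$accuracies[occ], 0.75)
  expect_equal(dia$counts[occ], 4)
  expect_equal(sum(dia$counts), 4)
})

test_that("a perfect confident predictor occupies only the top bin", {
  dia <- toy_diagram(rep(1, 5), rep(1, 5))
  expect_equal(which(dia$counts > 0), 10L)
  expect_equal(dia$confidences[10], 1)
  expect_equal(dia$accuracies[10], 1)
  expect_equal(expected_calibration_error(dia), 0)
})

test_that("bin confidences sit inside their bin edges; counts sum to N", {
  set.seed(5)
  conf <- runif(5000)
  gt <- rbinom(5000, 1, conf)
  dia <- toy_diagram(conf, gt, M = 7)
  expect_equal(sum(dia$counts), 5000)
  occ <- which(dia$counts > 0)
  expect_true(all(dia$confidences[occ] >= dia$bin_edges[occ] - 1e-12))
  expect_true(all(dia$confidences[occ] <= dia$bin_edges[occ + 1] + 1e-12))
})

test_that("calibrated Bernoulli draws give small per-bin gaps (LLN)", {
  set.seed(11)
  n <- 2e5
  conf <- runif(n)
  gt <- rbinom(n, 1, conf)
  dia <- toy_diagram(conf, gt)
  occ <- which(dia$counts > 0)
  expect_true(all(abs(dia$confidences[occ] - dia$accuracies[occ]) < 0.02))
})

test_that("diagram validation rejects bad input", {
  expect_error(toy_diagram(rep(0.5, 4), rep(1, 4), M = 1), "M must be")
  expect_error(toy_diagram(rep(0.5, 4), rep(1, 4), mask = rep(FALSE, 4)),
               "empty")
  expect_error(toy_diagram(c(0.5, 1.4), c(1, 1)), "\\[0, 1\\]")
})

test_that("ECE matches hand evaluation and a brute-force oracle", {
  # single-bin hand case: c = 0.8, a = 0.75 -> ECE 0.05
  dia <- toy_diagram(rep(0.8, 4), c(1, 1, 1, 0))
  expect_equal(expected_calibration_error(dia), 0.05)
  # random instances vs naive loop oracle
  set.seed(21)
  for (k in 1:25) {
    n <- sample(20:400, 1); M <- sample(2:15, 1)
    conf <- runif(n); gt <- rbinom(n, 1, conf)
    dia <- toy_diagram(conf, gt, M = M)
    expect_equal(expected_calibration_error(dia), ece_oracle(conf, gt, M),
                 tolerance = 1e-12)
    expect_equal(average_calibration_error(dia), ace_oracle(conf, gt, M),
                 tolerance = 1e-12)
  }
})

test_that("ACE: two-bin mean and the weighting counterexample vs ECE", {
  # two occupied bins with gaps 0.1 and 0.5 -> ACE 0.3
  conf <- c(rep(0.1, 10), rep(0.9, 10))
  gt <- c(rep(0, 10), rep(1, 4), rep(0, 6))    # gaps 0.1 and |0.9-0.4|=0.5
  dia <- toy_diagram(conf, gt)
  expect_equal(average_calibration_error(dia), mean(c(0.1, 0.5)))
  # huge accurate bin + tiny inaccurate bin -> ACE > ECE
  conf <- c(rep(0.55, 995), rep(0.05, 5))
  gt <- c(rep(1, 547), rep(0, 995 - 547), rep(1, 5))
  dia <- toy_diagram(conf, gt)
  expect_gt(average_calibration_error(dia), expected_calibration_error(dia))
})

test_that("ECE/ACE are invariant to voxel order and bounded", {
  set.seed(3)
  conf <- runif(300); gt <- rbinom(300, 1, 0.4)
  d1 <- toy_diagram(conf, gt)
  p <- sample(300)
  d2 <- toy_diagram(conf[p], gt[p])
  expect_equal(expected_calibration_error(d1), expected_calibration_error(d2))
  expect_equal(average_calibration_error(d1), average_calibration_error(d2))
  gaps <- abs(d1$confidences - d1$accuracies)
  expect_lte(expected_calibration_error(d1), max(gaps, na.rm = TRUE))
  expect_gte(expected_calibration_error(d1), 0)
})

test_that("dataset scope pools voxels across subjects", {
  d <- c(4, 4, 2)
  set.seed(9)
  confs <- lapply(1:3, function(i) array(runif(32), d))
  gts <- lapply(confs, function(cf) array(rbinom(32, 1, cf), d))
  pooled <- reliability_diagram(confs, gts, M = 5, scope = "dataset")
  manual <- toy_diagram(unlist(confs), unlist(gts), M = 5)
  expect_equal(pooled$counts, manual$counts)
  expect_equal(pooled$confidences, manual$confidences)
  expect_equal(pooled$accuracies, manual$accuracies)
  expect_error(reliability_diagram(confs, gts, M = 5, scope = "subject"),
               "exactly one")
})

test_that("temperature distortion drives the calibration classification", {
  set.seed(13)
  n <- 5e4
  # latent calibrated foreground probability with mass at both extremes
  p <- plogis(rnorm(n, 0, 3))
  gt <- rbinom(n, 1, p)
  sharpen <- function(p, tau) plogis(qlogis(p) / tau)
  expect_equal(classify_subject_calibration(toy_diagram(p, gt)),
               "well_calibrated")
  expect_equal(classify_subject_calibration(toy_diagram(sharpen(p, 0.5), gt)),
               "overconfident")
  expect_equal(classify_subject_calibration(toy_diagram(sharpen(p, 2), gt)),
               "underconfident")
})

test_that("mean subject ECE averages per-subject values; dataset ECE can cancel", {
  # two artificial subjects with known ECEs average correctly
  d <- c(10, 1, 1)
  s_conf <- list(array(rep(0.8, 10), d), array(rep(0.8, 10), d))
  s_gt <- list(array(c(rep(1, 8), 0, 0), d), array(c(rep(1, 6), rep(0, 4)), d))
  e1 <- expected_calibration_error(reliability_diagram(s_conf[[1]], s_gt[[1]]))
  e2 <- expected_calibration_error(reliability_diagram(s_conf[[2]], s_gt[[2]]))
  expect_equal(e1, 0)        # a = 0.8 exactly
  expect_equal(e2, 0.2)
  expect_equal(mean(c(e1, e2)), 0.1)
  # opposite miscalibrations cancel when pooled
  set.seed(31)
  n <- 2e4
  p <- plogis(rnorm(n, 0, 2)); gt1 <- rbinom(n, 1, p)
  over <- plogis(qlogis(p) / 0.5); under <- plogis(qlogis(p) / 2)
  d3 <- c(n, 1, 1)
  pooled <- reliability_diagram(list(array(over, d3), array(under, d3)),
                                list(array(gt1, d3), array(gt1, d3)),
                                scope = "dataset")
  e_over <- expected_calibration_error(toy_diagram(over, gt1))
  e_under <- expected_calibration_error(toy_diagram(under, gt1))
  expect_lt(expected_calibration_error(pooled), mean(c(e_over, e_under)))
})
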