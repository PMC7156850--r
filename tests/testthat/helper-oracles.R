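# Shared fixtures and independent brute-force oracles. Oracles are written
# as directly as possible (loops, exhaustive pair counting) so they stay
# independent of the package's vectorized implementations.

make_ball <- function(dims, radius, center = (dims + 1) / 2) {
  ix <- slice.index(array(0, dims), 1)
  iy <- slice.index(array(0, dims), 2)
  iz <- slice.index(array(0, dims), 3)
  (ix - center[1])^2 + (iy - center[2])^2 + (iz - center[3])^2 <= radius^2
}

make_box <- function(dims, from, to) {
  a <- array(FALSE, dims)
  a[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  a
}

# small synthetic spec for fast unit tests
small_spec <- function(...) {
  args <- list(dims = c(48, 48, 36), wt_radius_range = c(5, 7),
               boundary_sigma_mm = 1.5, noise_amplitude = 0.5,
               blob_radius_mm = 4, blob_min_distance_mm = 6,
               blob_unc_radius_mm = 3, blob_count_range = c(1, 2),
               blob_unc_count_range = c(1, 2), center_frac = 0.15)
  do.call(cohort_spec, utils::modifyList(args, list(...)))
}

# --- oracles ---------------------------------------------------------------

ece_oracle <- function(conf, gt, M) {
  # naive per-bin loops over a vector of confidences/labels
  n <- length(conf)
  total <- 0
  for (m in seq_len(M)) {
    lo <- (m - 1) / M; hi <- m / M
    inbin <- if (m == 1) conf >= lo & conf <= hi else conf > lo & conf <= hi
    nm <- sum(inbin)
    if (nm == 0) next
    total <- total + nm / n * abs(mean(conf[inbin]) - mean(gt[inbin]))
  }
  total
}

ace_oracle <- function(conf, gt, M) {
  gaps <- c()
  for (m in seq_len(M)) {
    lo <- (m - 1) / M; hi <- m / M
    inbin <- if (m == 1) conf >= lo & conf <= hi else conf > lo & conf <= hi
    if (sum(inbin) == 0) next
    gaps <- c(gaps, abs(mean(conf[inbin]) - mean(gt[inbin])))
  }
  mean(gaps)
}

dice_oracle <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (!any(a) && !any(b)) return(1)
  if (!any(a) || !any(b)) return(0)
  2 * sum(a & b) / (sum(a) + sum(b))
}

ue_oracle <- function(q, E, thr) {
  U <- as.vector(q) >= thr
  E <- as.vector(as.logical(E))
  dice_oracle(U, E)
}

# probabilistic AUC by exhaustive pair comparison; failures have low scores
auc_pair_oracle <- function(scores, failed) {
  f <- scores[failed]; s <- scores[!failed]
  tot <- 0
  for (x in f) for (y in s) tot <- tot + (x < y) + 0.5 * (x == y)
  tot / (length(f) * length(s))
}

# AUC-PR by explicit threshold scan over distinct scores (step interpolation)
aucpr_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels)
  prev_rec <- 0; total <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel]); prec <- tp / sum(sel); rec <- tp / P
    total <- total + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  total
}

spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

youden_scan_oracle <- function(scores, failed) {
  # exhaustive scan over midpoint thresholds: predicted failure = score < t
  cand <- sort(unique(scores))
  mids <- c(min(cand) - 1, (head(cand, -1) + cand[-1]) / 2, max(cand) + 1)
  best <- -Inf; best_acc <- NA
  for (t in mids) {
    pf <- scores < t
    sens <- if (any(failed)) mean(pf[failed]) else NA
    spec <- if (any(!failed)) mean(!pf[!failed]) else NA
    j <- sens - (1 - spec)
    if (j > best + 1e-12) { best <- j; best_acc <- mean(pf == failed) }
  }
  list(j = best, accuracy = best_acc)
}
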