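# Voxel-wise uncertainty and confidence maps.

#' Uncertainty map container
#'
#' A voxel-wise scalar field in \[0, 1\] together with its provenance:
#' `"entropy_from_prob"` for maps derived from foreground probabilities via
#' [normalized_entropy()], `"native"` for maps produced directly by an
#' uncertainty-native method (e.g. a variance head or an auxiliary
#' error-prediction network) after cohort-level normalization.
#'
#' @param values 3D array in \[0, 1\].
#' @param provenance `"entropy_from_prob"` or `"native"`.
#' @param region region name the map belongs to.
#' @return object of class `uq_uncertainty`.
#' @export
uncertainty_map <- function(values, provenance = c("entropy_from_prob", "native"),
                            region = NA_character_) {
  provenance <- match.arg(provenance)
  assert_volume(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("uncertainty values must be finite", call. = FALSE)
  rng <- range(values)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop(sprintf("uncertainty values must lie in [0,1]; range [%g, %g]",
                 rng[1], rng[2]), call. = FALSE)
  values[] <- pmin(pmax(values, 0), 1)
  structure(list(values = values, provenance = provenance, region = region),
            class = "uq_uncertainty")
}

#' @export
print.uq_uncertainty <- function(x, ...) {
  cat(sprintf("<uq_uncertainty> region %s, %s, grid %s, mean %.4f\n",
              x$region, x$provenance, paste(dim(x$values), collapse = "x"),
              mean(x$values)))
  invisible(x)
}

#' Normalized entropy of a foreground probability map
#'
#' Binary entropy in bits, `H = -[p log p + (1-p) log(1-p)] / log 2`, with
#' the convention `0 log 0 = 0`, so `H` lies in \[0, 1\] with its maximum 1
#' at p = 0.5 and 0 at p = 0 or 1. This is the standard uncertainty measure
#' for sigmoid-output segmentation models, for Monte-Carlo dropout and for
#' ensembles (applied to the sample-averaged probability).
#'
#' @param p probability volume (or vector) in \[0, 1\].
#' @param region region name carried into the result.
#' @param tol rejection tolerance for out-of-range inputs.
#' @return an `uq_uncertainty` with provenance `"entropy_from_prob"` if `p`
#'   is a 3D array, otherwise a bare numeric vector of entropies.
#' @export
normalized_entropy <- function(p, region = NA_character_, tol = 1e-9) {
  rng <- range(p)
  if (anyNA(p) || rng[1] < -tol || rng[2] > 1 + tol)
    stop(sprintf("probabilities must lie in [0,1]; range [%g, %g]",
                 rng[1], rng[2]), call. = FALSE)
  eps <- 1e-12
  pc <- pmin(pmax(p, eps), 1 - eps)
  h <- -(pc * log(pc) + (1 - pc) * log(1 - pc)) / log(2)
  h[p <= 0 | p >= 1] <- 0   # exact 0 log 0 convention at the endpoints
  h <- pmin(pmax(h, 0), 1)
  if (is.array(p) && length(dim(p)) == 3L) {
    h <- array(h, dim(p))
    uncertainty_map(h, "entropy_from_prob", region)
  } else {
    as.numeric(h)
  }
}

#' Average a stack of probability samples
#'
#' Voxel-wise arithmetic mean of T probability samples, as used to combine
#' Monte-Carlo dropout samples or ensemble members into a single foreground
#' probability per region.
#'
#' @param samples list of probability volumes (all one shape), or a 4D array
#'   with samples along the 4th dimension.
#' @return probability volume (3D array).
#' @export
combine_samples <- function(samples) {
  if (is.array(samples) && length(dim(samples)) == 4L) {
    samples <- lapply(seq_len(dim(samples)[4]), function(t)
      array(samples[, , , t], dim(samples)[1:3]))
  }
  if (!is.list(samples) || length(samples) < 1L)
    stop("need at least one probability sample", call. = FALSE)
  ref <- samples[[1]]
  assert_volume(ref, "samples[[1]]")
  acc <- array(0, dim(ref))
  for (s in samples) {
    assert_same_shape(ref, s, "samples[[1]]", "a later sample")
    assert_probability(s, "sample")
    acc <- acc + s
  }
  acc / length(samples)
}

#' Cohort-global extrema of native uncertainty values
#'
#' Scans all subjects of a cohort and returns the global minimum and
#' maximum of the raw native map for one region. Needed by
#' [normalize_native_map()], which by design normalizes over all subjects
#' of the cohort rather than per subject.
#'
#' @param raw_maps list of numeric volumes (one per subject), or a function
#'   `function(i)` returning subject i's raw volume plus `n`, the count.
#' @param n number of subjects when `raw_maps` is a function.
#' @return list with `min` and `max`.
#' @export
native_extrema <- function(raw_maps, n = NULL) {
  if (is.function(raw_maps)) {
    stopifnot(!is.null(n))
    mn <- Inf; mx <- -Inf
    for (i in seq_len(n)) {
      v <- raw_maps(i)
      mn <- min(mn, min(v)); mx <- max(mx, max(v))
    }
  } else {
    mn <- min(vapply(raw_maps, min, numeric(1)))
    mx <- max(vapply(raw_maps, max, numeric(1)))
  }
  list(min = mn, max = mx)
}

#' Min-max normalize a native uncertainty map with cohort-global extrema
#'
#' Rescales a nonnegative raw map (e.g. a predicted variance) to \[0, 1\]
#' using extrema computed over all subjects of the cohort — per-subject
#' normalization would make maps incomparable across subjects and is
#' deliberately rejected. A cohort whose values are all equal maps to
#' all-zeros (degenerate-range convention).
#'
#' @param values raw nonnegative volume for one subject.
#' @param extrema cohort-global extrema from [native_extrema()]; required.
#' @param region region name.
#' @return an `uq_uncertainty` with provenance `"native"`.
#' @export
normalize_native_map <- function(values, extrema, region = NA_character_) {
  assert_volume(values)
  if (anyNA(values) || any(!is.finite(values)) || min(values) < 0)
    stop("native values must be finite and >= 0", call. = FALSE)
  if (missing(extrema) || is.null(extrema))
    stop(paste0("cohort-global extrema are required; per-subject ",
                "normalization is not supported"), call. = FALSE)
  rng <- extrema$max - extrema$min
  if (rng <= 0) {
    out <- array(0, dim(values))
  } else {
    out <- (values - extrema$min) / rng
    out[] <- pmin(pmax(out, 0), 1)
  }
  uncertainty_map(out, "native", region)
}

#' Translate uncertainty into a foreground-probability surrogate
#'
#' Maps an uncertainty map q and a predicted binary label y to confidence
#' values `y (1 - 0.5 q) + (1 - y) 0.5 q`: predicted-foreground voxels get
#' confidence in \[0.5, 1\] (1 when certain), predicted-background voxels
#' in \[0, 0.5\]. This makes uncertainty-native methods comparable to
#' probability-output methods on one calibration axis.
#'
#' @param q an `uq_uncertainty` or bare volume in \[0, 1\].
#' @param y predicted binary label volume.
#' @return probability-like volume (3D array).
#' @export
uncertainty_to_confidence <- function(q, y) {
  qv <- if (inherits(q, "uq_uncertainty")) q$values else q
  assert_volume(qv, "q")
  assert_probability(qv, "q")
  assert_binary(y)
  assert_same_shape(qv, y, "q", "y")
  ym <- as_mask(y)
  out <- 0.5 * qv
  out[ym] <- 1 - 0.5 * qv[ym]
  out
}

#' Per-subject uncertainty for a region, deriving entropy when needed
#'
#' Returns the subject's stored uncertainty map for `region` if present,
#' otherwise derives one as the normalized entropy of the stored
#' probability map.
#'
#' @param subject a `uq_subject`.
#' @param region region name.
#' @return an `uq_uncertainty`.
#' @export
subject_uncertainty <- function(subject, region) {
  u <- subject$uncertainty_maps[[region]]
  if (!is.null(u)) return(u)
  p <- subject$prob_maps[[region]]
  if (is.null(p))
    stop("subject ", subject$subject_id, " has neither uncertainty nor ",
         "probability map for region ", region, call. = FALSE)
  normalized_entropy(p, region = region)
}

#' Per-subject confidence (foreground-probability axis) for a region
#'
#' The stored probability map when available; otherwise the stored native
#' uncertainty translated via [uncertainty_to_confidence()] with the
#' predicted label.
#'
#' @param subject a `uq_subject`.
#' @param region region name.
#' @return probability volume.
#' @export
subject_confidence <- function(subject, region) {
  p <- subject$prob_maps[[region]]
  if (!is.null(p)) return(p)
  u <- subject$uncertainty_maps[[region]]
  if (is.null(u))
    stop("subject ", subject$subject_id, " has neither probability nor ",
         "uncertainty map for region ", region, call. = FALSE)
  uncertainty_to_confidence(u, subject$pred_labels[[region]])
}
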