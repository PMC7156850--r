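# Seeded synthetic brain-tumor-like cohorts. Subjects carry nested
# hierarchical regions (ET ⊆ TC ⊆ WT) inside an ellipsoidal brain mask,
# probability maps whose calibration is controlled by a per-subject
# temperature, boundary-localized uncertainty, and injectable failure
# modes (remote high-confidence blobs, missed core, boundary jitter) that
# decouple mean uncertainty from segmentation quality. Every subject is a
# pure function of (spec, master seed, subject index).

#' Specification of a synthetic cohort
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: a 96 x 96 x 64 grid at 1 mm isotropic spacing, an ellipsoidal
#' brain of roughly 250k voxels, whole-tumor radii 8-14 mm with smooth
#' low-frequency deformation, 2 mm boundary blur, and a clean cohort
#' (failure modes and miscalibration are opted into per experiment).
#'
#' @param n_subjects number of subjects.
#' @param dims grid shape (3 integers).
#' @param spacing voxel size in mm.
#' @param brain_frac brain ellipsoid semi-axes as a fraction of `dims/2`.
#' @param brain_scale_range per-subject uniform scaling range of the brain
#'   semi-axes (head sizes differ across subjects).
#' @param wt_radius_range min/max whole-tumor base radius (mm).
#' @param tc_frac,et_frac tumor-core and enhancing-tumor radii as fractions
#'   of the WT radius (nesting is guaranteed by construction).
#' @param deform_amplitude relative amplitude of the low-frequency radial
#'   deformation (0 = exact nested ellipsoids).
#' @param center_frac how far from the brain centre a tumour may sit, as a
#'   fraction of the brain semi-axes.
#' @param boundary_sigma_mm Gaussian blur (mm) applied to the ground truth
#'   to obtain the latent probability field; sets the width of the
#'   boundary uncertainty rim. A length-2 vector gives a per-subject
#'   uniform range (sharper or fuzzier boundaries per case).
#' @param tau per-subject temperature: scalar (recycled), vector of length
#'   `n_subjects`, or a function `n -> values`. tau < 1 gives
#'   over-confident maps, tau > 1 under-confident.
#' @param mode `"morphology"` (deterministic gt, noisy boundary; clean
#'   shapes for aggregation experiments) or `"calibration"` (ground truth
#'   redrawn voxel-wise as Bernoulli of the latent field, which makes the
#'   latent field perfectly calibrated by construction).
#' @param noise_amplitude logit-space amplitude of the smooth morphology
#'   noise (morphology mode only; 0 = prediction equals gt). A length-2
#'   vector gives a per-subject uniform range, so subjects differ in
#'   difficulty the way clinical cases do.
#' @param noise_wavelength_mm correlation scale of that noise.
#' @param failure_mix named fractions over
#'   `c("clean", "remote_blob", "missed_core", "boundary_jitter")`;
#'   must sum to 1.
#' @param blob_count_range,blob_radius_mm,blob_prob,blob_edge_sigma_mm,blob_min_distance_mm
#'   remote-blob parameters: number of blobs (range), radius, interior
#'   confidence (high = low blob uncertainty), edge blur, and minimum
#'   distance from the whole tumor.
#' @param blob_unc_prob,blob_unc_radius_mm,blob_unc_count_range remote
#'   uncertainty-only patches
#'   accompanying the confident blobs: probability peak (kept below 0.5 so
#'   predictions are unchanged, but normalized entropy is near 1) and
#'   radius. Failed segmentations show diffuse uncertainty far from any
#'   predicted boundary; these patches model that signature and are what
#'   distance-based aggregation keys on. Set `blob_unc_prob = 0` to
#'   disable.
#' @param missed_prob probability written into the suppressed core.
#' @param jitter_amplitude extra logit noise for boundary_jitter subjects.
#' @param native_uncertainty if TRUE subjects carry native uncertainty
#'   maps (and no probability maps), emulating uncertainty-native methods.
#' @param split_fractions named train/validation/test fractions.
#' @param seed master seed; the whole cohort is a pure function of it.
#' @return object of class `uq_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 100,
                        dims = c(96, 96, 64),
                        spacing = c(1, 1, 1),
                        brain_frac = 0.94,
                        brain_scale_range = c(0.92, 1.06),
                        wt_radius_range = c(8, 12),
                        tc_frac = 0.65,
                        et_frac = 0.45,
                        deform_amplitude = 0.2,
                        center_frac = 0.2,
                        boundary_sigma_mm = c(1.5, 2.5),
                        tau = 1,
                        mode = c("morphology", "calibration"),
                        noise_amplitude = c(0.25, 0.6),
                        noise_wavelength_mm = 20,
                        failure_mix = c(clean = 1),
                        blob_count_range = c(2, 3),
                        blob_radius_mm = 6,
                        blob_prob = 0.99,
                        blob_edge_sigma_mm = 0.5,
                        blob_min_distance_mm = 10,
                        blob_unc_prob = 0.45,
                        blob_unc_radius_mm = 3,
                        blob_unc_count_range = c(2, 3),
                        missed_prob = 0.05,
                        jitter_amplitude = 2,
                        native_uncertainty = FALSE,
                        split_fractions = c(train = 0.35, validation = 0.09,
                                            test = 0.56),
                        seed = 1L) {
  mode <- match.arg(mode)
  spec <- list(n_subjects = as.integer(n_subjects), dims = as.integer(dims),
               spacing = as.numeric(spacing), brain_frac = brain_frac,
               brain_scale_range = brain_scale_range,
               wt_radius_range = wt_radius_range, tc_frac = tc_frac,
               et_frac = et_frac, deform_amplitude = deform_amplitude,
               center_frac = center_frac,
               boundary_sigma_mm = boundary_sigma_mm, tau = tau, mode = mode,
               noise_amplitude = noise_amplitude,
               noise_wavelength_mm = noise_wavelength_mm,
               failure_mix = failure_mix,
               blob_count_range = blob_count_range,
               blob_radius_mm = blob_radius_mm, blob_prob = blob_prob,
               blob_edge_sigma_mm = blob_edge_sigma_mm,
               blob_min_distance_mm = blob_min_distance_mm,
               blob_unc_prob = blob_unc_prob,
               blob_unc_radius_mm = blob_unc_radius_mm,
               blob_unc_count_range = blob_unc_count_range,
               missed_prob = missed_prob,
               jitter_amplitude = jitter_amplitude,
               native_uncertainty = native_uncertainty,
               split_fractions = split_fractions, seed = as.integer(seed),
               regions = REGIONS)
  class(spec) <- "uq_cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (abs(sum(spec$failure_mix) - 1) > 1e-8)
    stop("failure_mix fractions must sum to 1", call. = FALSE)
  bad <- setdiff(names(spec$failure_mix),
                 c("clean", "remote_blob", "missed_core", "boundary_jitter"))
  if (length(bad) > 0)
    stop("unknown failure mode(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(spec$noise_amplitude < 0) || length(spec$noise_amplitude) > 2)
    stop("noise_amplitude must be a scalar or range of nonnegative values",
         call. = FALSE)
  if (is.numeric(spec$tau) && any(spec$tau <= 0))
    stop("tau must be > 0", call. = FALSE)
  if (abs(sum(spec$split_fractions) - 1) > 1e-8 ||
      any(spec$split_fractions < 0))
    stop("split fractions must be nonnegative and sum to 1", call. = FALSE)
  if (any(spec$failure_mix < 0))
    stop("failure_mix fractions must be nonnegative", call. = FALSE)
  semi <- spec$brain_frac * min(spec$brain_scale_range) *
    spec$dims * spec$spacing / 2
  reach <- max(spec$wt_radius_range) * (1 + spec$deform_amplitude) +
    3 * max(spec$boundary_sigma_mm)
  room <- min(semi) * (1 - spec$center_frac)
  if (reach > room)
    stop(sprintf(paste0("infeasible nesting: tumour reach %.1f mm exceeds ",
                        "the %.1f mm available inside the brain"),
         reach, room), call. = FALSE)
  invisible(spec)
}

#' @export
print.uq_cohort_spec <- function(x, ...) {
  cat(sprintf("<uq_cohort_spec> n = %d, grid %s @ %s mm, mode %s, seed %d\n",
              x$n_subjects, paste(x$dims, collapse = "x"),
              paste(x$spacing, collapse = "x"), x$mode, x$seed))
  invisible(x)
}

# physical voxel-centre coordinate arrays (0-based indices times spacing);
# optionally restricted to an index window (list of per-axis index vectors)
coord_arrays <- function(dims, spacing, window = NULL) {
  ix <- lapply(1:3, function(ax) {
    w <- if (is.null(window)) seq_len(dims[ax]) else window[[ax]]
    (w - 1) * spacing[ax]
  })
  d <- vapply(ix, length, integer(1))
  list(x = array(rep(ix[[1]], times = d[2] * d[3]), d),
       y = array(rep(rep(ix[[2]], each = d[1]), times = d[3]), d),
       z = array(rep(ix[[3]], each = d[1] * d[2]), d))
}

# per-axis index window covering `mask` (or a centre+radius ball) plus pad
bbox_window <- function(dims, mask = NULL, center = NULL, radius = NULL,
                        spacing = c(1, 1, 1), pad = 2L) {
  lo <- integer(3); hi <- integer(3)
  if (!is.null(mask)) {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0) return(lapply(dims, seq_len))
    lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
    lo <- lo - pad; hi <- hi + pad
  } else {
    lo <- floor(center / spacing - radius / spacing) + 1L - pad
    hi <- ceiling(center / spacing + radius / spacing) + 1L + pad
  }
  lapply(1:3, function(ax)
    max(1L, lo[ax]):min(dims[ax], hi[ax]))
}

# paste a subvolume computed on `window` into a full-size array
paste_window <- function(full, sub, window) {
  full[window[[1]], window[[2]], window[[3]]] <- sub
  full
}

crop_window <- function(a, window) a[window[[1]], window[[2]], window[[3]],
                                     drop = FALSE]

# full-grid coordinate arrays are reused across subjects; cache per geometry
.coord_cache <- new.env(parent = emptyenv())
coord_arrays_cached <- function(dims, spacing) {
  key <- paste(c(dims, spacing), collapse = "_")
  if (is.null(.coord_cache[[key]]))
    .coord_cache[[key]] <- coord_arrays(dims, spacing)
  .coord_cache[[key]]
}

brain_mask_for <- function(spec, scale = 1) {
  co <- coord_arrays_cached(spec$dims, spec$spacing)
  ctr <- (spec$dims - 1) * spec$spacing / 2
  semi <- scale * spec$brain_frac * spec$dims * spec$spacing / 2
  ((co$x - ctr[1]) / semi[1])^2 + ((co$y - ctr[2]) / semi[2])^2 +
    ((co$z - ctr[3]) / semi[3])^2 <= 1
}

# smooth random field: sum of low-frequency cosine modes, unit sd, seeded
smooth_field <- function(co, wavelength_mm, n_modes = 8) {
  acc <- 0
  for (k in seq_len(n_modes)) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    wl <- wavelength_mm * runif(1, 0.7, 1.4)
    om <- 2 * pi / wl
    ph <- runif(1, 0, 2 * pi)
    acc <- acc + rnorm(1) * cos(om * (dir[1] * co$x + dir[2] * co$y +
                                        dir[3] * co$z) + ph)
  }
  acc / sqrt(sum(rep(0.5, n_modes)))  # approximate unit variance
}

#' Generate one phantom: nested tumor labels inside a brain mask
#'
#' A smooth random blob (ellipsoid radius modulated by a low-frequency
#' deformation field) defines the whole tumor; the tumor core and
#' enhancing tumor reuse the same deformation with smaller radii, so
#' ET is contained in TC is contained in WT holds by construction. Zero deformation
#' amplitude gives exact nested spheres.
#'
#' @param spec a `uq_cohort_spec`.
#' @param subject_seed integer seed for this subject's shape.
#' @return list with `gt` (named list WT/TC/ET), `brain_mask`, `center`,
#'   `wt_radius`.
#' @export
generate_phantom <- function(spec, subject_seed) {
  withr::with_seed(subject_seed, {
    dims <- spec$dims; sp <- spec$spacing
    ctr <- (dims - 1) * sp / 2
    scl <- runif(1, spec$brain_scale_range[1], spec$brain_scale_range[2])
    brain <- brain_mask_for(spec, scl)
    semi <- scl * spec$brain_frac * dims * sp / 2

    off <- runif(3, -1, 1) * spec$center_frac * semi
    cx <- ctr + off
    r_wt <- runif(1, spec$wt_radius_range[1], spec$wt_radius_range[2])
    reach <- r_wt * (1 + spec$deform_amplitude) + 1
    win <- bbox_window(dims, center = cx, radius = reach, spacing = sp)
    co <- coord_arrays(dims, sp, win)
    dist <- sqrt((co$x - cx[1])^2 + (co$y - cx[2])^2 + (co$z - cx[3])^2)
    if (spec$deform_amplitude > 0) {
      g <- smooth_field(co, wavelength_mm = 4 * r_wt)
      mult <- pmax(1 + spec$deform_amplitude * g, 0.2)
    } else {
      mult <- 1
    }
    empty <- array(FALSE, dims)
    gt <- list(WT = paste_window(empty, dist <= r_wt * mult, win),
               TC = paste_window(empty, dist <= spec$tc_frac * r_wt * mult, win),
               ET = paste_window(empty, dist <= spec$et_frac * r_wt * mult, win))
    gt <- lapply(gt, function(m) m & brain)
    list(gt = gt, brain_mask = brain, center = cx, wt_radius = r_wt)
  })
}

#' Simulate a probabilistic predictor for a phantom
#'
#' The latent field is the Gaussian-blurred ground truth, clipped to
#' \[0, 1\] and restricted to the brain. In calibration mode the ground
#' truth is REDRAWN voxel-wise as Bernoulli of the latent field (one
#' shared uniform per voxel keeps the redrawn regions nested), so the
#' latent field is perfectly calibrated by construction; the reported
#' probability is the temperature-distorted latent field
#' `sigmoid(logit(p*) / tau)`. In morphology mode the ground truth is kept
#' and a smooth logit-space noise field jitters the decision boundary
#' instead. Predictions threshold the reported probability at 0.5 (and are
#' therefore invariant to tau).
#'
#' @param phantom output of [generate_phantom()].
#' @param spec a `uq_cohort_spec`.
#' @param subject_seed integer seed.
#' @param tau temperature for this subject.
#' @return list with `prob` (named list per region), `pred`, `gt`
#'   (possibly resampled), `brain_mask`.
#' @export
simulate_predictor <- function(phantom, spec, subject_seed, tau = 1) {
  if (tau <= 0) stop("tau must be > 0", call. = FALSE)
  withr::with_seed(subject_seed, {
    brain <- phantom$brain_mask
    gt <- phantom$gt
    dims <- spec$dims
    sigma <- if (length(spec$boundary_sigma_mm) == 2)
      runif(1, spec$boundary_sigma_mm[1], spec$boundary_sigma_mm[2])
    else spec$boundary_sigma_mm
    # all fields live in a window around the tumour; outside it the latent
    # field is exactly 0 (and so are probabilities and redrawn labels)
    pad <- ceiling(3 * sigma / min(spec$spacing)) + 2L
    win <- bbox_window(dims, mask = gt$WT, pad = pad)
    brain_w <- crop_window(brain, win)
    zero <- array(0, dims)
    pstar_w <- lapply(gt, function(m) {
      p <- gaussian_blur3(crop_window(m, win) * 1.0, sigma, spec$spacing)
      pmin(pmax(p, 0), 1) * brain_w
    })
    if (spec$mode == "calibration") {
      u <- array(runif(length(pstar_w[[1]])), dim(pstar_w[[1]]))
      gt <- lapply(pstar_w, function(p)
        paste_window(array(FALSE, dims), u < p, win))  # shared u: nested
      phat_w <- lapply(pstar_w, function(p) sigmoid(logit(p) / tau))
    } else {
      amp <- if (length(spec$noise_amplitude) == 2)
        runif(1, spec$noise_amplitude[1], spec$noise_amplitude[2])
      else spec$noise_amplitude
      if (amp > 0) {
        eta <- smooth_field(coord_arrays(dims, spec$spacing, win),
                            spec$noise_wavelength_mm) * amp
      } else {
        eta <- 0
      }
      phat_w <- lapply(pstar_w, function(p) sigmoid((logit(p) + eta) / tau))
    }
    phat <- lapply(phat_w, function(p) {
      p[p < 1e-6] <- 0           # exact zero far from the tumour
      paste_window(zero, p * brain_w, win)
    })
    pred <- lapply(phat, function(p) p >= 0.5)
    list(prob = phat, pred = pred, gt = gt, brain_mask = brain)
  })
}

#' Inject a failure mode into a simulated subject
#'
#' * `remote_blob`: raises the WT probability above 0.5 in
#'   `n` spheres placed at least `blob_min_distance_mm` from the whole
#'   tumor, with interior confidence `blob_prob` (high-confidence blobs
#'   leave the mean uncertainty almost unchanged while Dice drops).
#' * `missed_core`: suppresses the TC probability inside the half of the
#'   tumor core on the positive-x side of its centroid.
#' * `boundary_jitter`: extra smooth logit noise that perturbs the
#'   prediction near the surface; amplitude 0 leaves the subject unchanged.
#'
#' Predictions are recomputed from the corrupted probabilities.
#'
#' @param sim output of [simulate_predictor()].
#' @param mode one of `"clean"`, `"remote_blob"`, `"missed_core"`,
#'   `"boundary_jitter"`.
#' @param spec a `uq_cohort_spec`.
#' @param subject_seed integer seed.
#' @return `sim` with corrupted `prob`/`pred` and a `failure` provenance
#'   record (mode + parameters actually applied).
#' @export
inject_failure <- function(sim, mode, spec, subject_seed) {
  if (mode == "clean") {
    sim$failure <- list(mode = "clean")
    return(sim)
  }
  withr::with_seed(subject_seed, {
    if (mode == "remote_blob") {
      rb <- spec$blob_radius_mm
      ru <- spec$blob_unc_radius_mm
      n_blobs <- sample(spec$blob_count_range[1]:spec$blob_count_range[2], 1)
      n_unc <- if (spec$blob_unc_prob > 0)
        sample(spec$blob_unc_count_range[1]:spec$blob_unc_count_range[2], 1)
      else 0L
      rmax <- max(rb, ru)
      d_wt <- distance_transform(sim$gt$WT, spec$spacing)
      d_out <- distance_transform(!sim$brain_mask, spec$spacing)
      cand <- which(d_wt >= spec$blob_min_distance_mm + rmax &
                      d_out >= rmax + 2)
      if (length(cand) < 1)
        stop("no feasible remote-blob location for this subject", call. = FALSE)
      co <- coord_arrays_cached(spec$dims, spec$spacing)
      centers <- list(); tries <- 0
      while (length(centers) < n_blobs + n_unc && tries < 400) {
        tries <- tries + 1
        idx <- cand[sample.int(length(cand), 1)]
        pos <- c(co$x[idx], co$y[idx], co$z[idx])
        ok <- all(vapply(centers, function(c0)
          sqrt(sum((c0 - pos)^2)) >= 2 * rmax, logical(1)))
        if (ok) centers[[length(centers) + 1L]] <- pos
      }
      if (length(centers) == 0)
        stop("could not place any remote blob after retries", call. = FALSE)
      n_blobs <- min(n_blobs, length(centers))
      paint <- function(centers, radius, sigma) {
        field <- array(0, spec$dims)
        for (c0 in centers) {
          sph <- (co$x - c0[1])^2 + (co$y - c0[2])^2 +
            (co$z - c0[3])^2 <= radius^2
          field <- pmax(field, sph * 1.0)
        }
        pad <- ceiling(3 * sigma / min(spec$spacing)) + 2L
        bwin <- bbox_window(spec$dims, mask = field > 0, pad = pad)
        bw <- gaussian_blur3(crop_window(field, bwin), sigma, spec$spacing)
        paste_window(field, bw / max(bw), bwin)
      }
      # confident false-positive cores: Dice drops, uncertainty barely moves
      core <- paint(centers[seq_len(n_blobs)], rb, spec$blob_edge_sigma_mm)
      sim$prob$WT <- pmax(sim$prob$WT, spec$blob_prob * core * sim$brain_mask)
      # remote uncertainty-only patches: probability stays below 0.5 so the
      # prediction is unchanged, but entropy is ~1 far from any boundary
      if (n_unc > 0 && length(centers) > n_blobs) {
        unc_centers <- centers[(n_blobs + 1L):length(centers)]
        halo <- paint(unc_centers, ru, 0.8)
        sim$prob$WT <- pmax(sim$prob$WT,
                            spec$blob_unc_prob * halo * sim$brain_mask)
      } else {
        unc_centers <- list()
      }
      sim$failure <- list(mode = "remote_blob", n_blobs = n_blobs,
                          radius_mm = rb, blob_prob = spec$blob_prob,
                          centers = centers[seq_len(n_blobs)],
                          n_unc = length(unc_centers),
                          unc_centers = unc_centers,
                          blob_unc_prob = spec$blob_unc_prob)
    } else if (mode == "missed_core") {
      tc <- sim$gt$TC
      if (any(tc)) {
        co <- coord_arrays(spec$dims, spec$spacing)
        cx <- mean(co$x[tc])
        cut <- tc & (co$x >= cx)
        sim$prob$TC[cut] <- pmin(sim$prob$TC[cut], spec$missed_prob)
        sim$failure <- list(mode = "missed_core",
                            suppressed_voxels = sum(cut),
                            missed_prob = spec$missed_prob)
      } else {
        sim$failure <- list(mode = "missed_core", suppressed_voxels = 0)
      }
    } else if (mode == "boundary_jitter") {
      amp <- spec$jitter_amplitude
      if (amp > 0) {
        eta <- smooth_field(coord_arrays(spec$dims, spec$spacing),
                            spec$noise_wavelength_mm / 2) * amp
        sim$prob <- lapply(sim$prob, function(p)
          sigmoid(logit(p) + eta) * sim$brain_mask)
      }
      sim$failure <- list(mode = "boundary_jitter", amplitude = amp)
    } else {
      stop("unknown failure mode: ", mode, call. = FALSE)
    }
    sim$pred <- lapply(sim$prob, function(p) p >= 0.5)
    sim
  })
}

# build subject i of a synthetic cohort from its manifest row
synthesize_subject <- function(spec, i, row) {
  phantom <- generate_phantom(spec, derive_seed(spec$seed, i, 1L))
  sim <- simulate_predictor(phantom, spec, derive_seed(spec$seed, i, 2L),
                            tau = row$tau)
  sim <- inject_failure(sim, row$failure_mode, spec,
                        derive_seed(spec$seed, i, 3L))
  unc <- NULL; prob <- sim$prob
  if (isTRUE(spec$native_uncertainty)) {
    unc <- lapply(spec$regions, function(r)
      normalized_entropy(sim$prob[[r]], region = r))
    names(unc) <- spec$regions
    unc <- lapply(unc, function(u) { u$provenance <- "native"; u })
    prob <- NULL
  }
  subject_record(row$subject_id,
                 gt_labels = sim$gt, pred_labels = sim$pred,
                 brain_mask = sim$brain_mask, prob_maps = prob,
                 uncertainty_maps = unc, spacing = spec$spacing,
                 split = row$split,
                 check_hierarchy = spec$mode != "calibration")
}

#' Generate a synthetic cohort
#'
#' Samples per-subject temperature and failure mode, assigns splits by the
#' configured fractions, and returns a lazy cohort: subjects are
#' regenerated deterministically on demand by [cohort_subject()], so large
#' cohorts never hold all volumes in memory. The manifest records
#' subject_id, split, tau, failure_mode and (optionally) the true Dice per
#' region.
#'
#' @param spec a `uq_cohort_spec`.
#' @param compute_dice materialize each subject once to record true Dice
#'   in the manifest (costs one generation pass). Default TRUE.
#' @return a `uq_cohort` with `source = "synthetic"`.
#' @export
generate_cohort <- function(spec, compute_dice = TRUE) {
  stopifnot(inherits(spec, "uq_cohort_spec"))
  n <- spec$n_subjects
  tau <- spec$tau
  taus <- withr::with_seed(derive_seed(spec$seed, 0L, 4L), {
    if (is.function(tau)) tau(n) else rep_len(tau, n)
  })
  counts_mode <- largest_remainder(spec$failure_mix, n)
  modes <- withr::with_seed(derive_seed(spec$seed, 0L, 5L),
                            sample(rep(names(counts_mode), counts_mode)))
  counts_split <- largest_remainder(spec$split_fractions, n)
  splits <- rep(names(counts_split), counts_split)
  manifest <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    split = splits, tau = taus, failure_mode = modes)
  cohort <- structure(list(source = "synthetic", spec = spec,
                           manifest = manifest),
                      class = "uq_cohort")
  if (compute_dice) {
    dice <- matrix(NA_real_, n, length(spec$regions),
                   dimnames = list(NULL, paste0("true_dice_", spec$regions)))
    for (i in seq_len(n)) {
      s <- cohort_subject(cohort, i)
      for (k in seq_along(spec$regions)) {
        r <- spec$regions[k]
        dice[i, k] <- dice_coefficient(s$pred_labels[[r]], s$gt_labels[[r]])
      }
    }
    cohort$manifest <- dplyr::bind_cols(manifest, tibble::as_tibble(dice))
  }
  cohort
}

# integer apportionment of n among named fractions (largest remainder)
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}
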