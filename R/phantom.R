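# Synthetic speckle phantoms and preprocessing. The phantoms emulate the
# gross appearance of abdominal B-mode volumes: a speckle-textured
# parenchyma, a few dark tubular structures (vessels) following smooth
# random walks, and one bright curved sheet (diaphragm analog). Every
# generated object is deterministic given its seed, and every pair/sequence
# carries its exact ground-truth slicing pose.

#' Phantom generator configuration
#'
#' @param shape voxel grid size (length 3).
#' @param spacing isotropic voxel spacing in mm.
#' @param n_vessels number of tubular structures.
#' @param vessel_radius range (mm) of tube radii, `c(min, max)`.
#' @param background,vessel,diaphragm intensity levels in `[0, 1]`.
#' @param speckle_scale strength of the multiplicative speckle in `[0, 1]`
#'   (0 = none).
#' @param smooth_sigma Gaussian smoothing of the speckled image, mm.
#' @param mask_margin voxels stripped from the volume border in the validity
#'   mask (stand-in for the transducer fan boundary).
#' @param seed integer; the same seed reproduces the volume bit for bit.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(96, 96, 96), spacing = 0.5,
                           n_vessels = 4, vessel_radius = c(1.5, 3.5),
                           background = 0.5, vessel = 0.12, diaphragm = 0.95,
                           speckle_scale = 0.35, smooth_sigma = 0.8,
                           mask_margin = 2, seed = 1) {
  stopifnot(length(shape) == 3, all(shape > 0), spacing > 0,
            all(c(background, vessel, diaphragm) >= 0),
            all(c(background, vessel, diaphragm) <= 1))
  structure(list(shape = as.integer(shape), spacing = spacing,
                 n_vessels = n_vessels, vessel_radius = vessel_radius,
                 background = background, vessel = vessel,
                 diaphragm = diaphragm, speckle_scale = speckle_scale,
                 smooth_sigma = smooth_sigma, mask_margin = mask_margin,
                 seed = seed),
            class = "phantom_config")
}

# carve a tube of radius r (voxels) along a polyline of voxel coordinates
carve_tube <- function(lab, path, r) {
  d <- dim(lab)
  rr <- ceiling(r)
  off <- as.matrix(expand.grid(-rr:rr, -rr:rr, -rr:rr))
  off <- off[rowSums(off^2) <= r^2, , drop = FALSE]
  for (p in seq_len(nrow(path))) {
    ctr <- round(path[p, ])
    vox <- sweep(off, 2, ctr, "+")
    keep <- vox[, 1] >= 1 & vox[, 1] <= d[1] &
            vox[, 2] >= 1 & vox[, 2] <= d[2] &
            vox[, 3] >= 1 & vox[, 3] <= d[3]
    if (any(keep)) lab[vox[keep, , drop = FALSE]] <- 1
  }
  lab
}

#' Generate a synthetic speckle phantom volume
#'
#' Builds a liver-like test volume: smooth background parenchyma carrying
#' multiplicative speckle, dark random-walk vessel tubes, and one bright
#' curved diaphragm-like sheet. Intensities are clipped to `[0, 1]`; the
#' validity mask is the full grid minus a border margin.
#'
#' @param cfg a [phantom_config()].
#' @return an `image_volume` with attributes `vessel_label` and
#'   `diaphragm_label` (binary arrays marking the structures before speckle).
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(cfg$seed, {
    d <- cfg$shape
    # smooth low-frequency background modulation around the base level
    lowfreq <- array(rnorm(prod(d)), d)
    lowfreq <- .gauss_smooth3_cpp(lowfreq, rep(8, 3))
    lowfreq <- lowfreq / max(abs(lowfreq), 1e-12) * 0.08
    img <- array(cfg$background, d) + lowfreq

    # vessels: smooth random-walk tubes entering from a random face
    vessel_lab <- array(0, d)
    for (v in seq_len(cfg$n_vessels)) {
      start <- runif(3, 0.2, 0.8) * d
      axis <- sample(3, 1)
      start[axis] <- 2
      dir <- rnorm(3); dir[axis] <- abs(dir[axis]) + 1.5
      dir <- dir / sqrt(sum(dir^2))
      n_steps <- max(d) * 2
      path <- matrix(NA_real_, n_steps, 3)
      pos <- start
      for (s in seq_len(n_steps)) {
        path[s, ] <- pos
        dir <- dir + rnorm(3, sd = 0.12)
        dir <- dir / sqrt(sum(dir^2))
        pos <- pos + dir
        if (any(pos < 1) || any(pos > d)) { path <- path[seq_len(s), , drop = FALSE]; break }
      }
      r_mm <- runif(1, cfg$vessel_radius[1], cfg$vessel_radius[2])
      vessel_lab <- carve_tube(vessel_lab, path, r_mm / cfg$spacing)
    }
    img[vessel_lab == 1] <- cfg$vessel

    # diaphragm analog: one bright curved sheet z = f(x, y)
    thick <- max(1.5 / cfg$spacing, 1.5)
    cx <- (seq_len(d[1]) - d[1] / 2) / d[1]
    cy <- (seq_len(d[2]) - d[2] / 2) / d[2]
    zsurf <- outer(cx, cy, function(x, y) 0.8 * d[3] + runif(1, -0.1, 0.1) * d[3] -
                     (0.25 * x^2 + 0.2 * y^2) * d[3])
    zidx <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
    dist <- abs(zidx - array(rep(zsurf, d[3]), d))
    sheet <- pmax(0, 1 - dist / thick)
    diaphragm_lab <- array(as.numeric(dist <= thick), d)
    img <- img + (cfg$diaphragm - img) * sheet

    # multiplicative Rayleigh-like speckle, then smoothing
    if (cfg$speckle_scale > 0) {
      ray <- sqrt(-2 * log(runif(prod(d))))      # Rayleigh(1) draws
      ray <- ray / sqrt(pi / 2)                  # unit mean
      img <- img * (1 - cfg$speckle_scale + cfg$speckle_scale * array(ray, d))
    }
    if (cfg$smooth_sigma > 0) {
      img <- .gauss_smooth3_cpp(img, rep(cfg$smooth_sigma / cfg$spacing, 3))
    }
    img <- pmin(pmax(img, 0), 1)   # argument order keeps the dim attribute

    mask <- array(0, d)
    m <- cfg$mask_margin
    mask[(1 + m):(d[1] - m), (1 + m):(d[2] - m), (1 + m):(d[3] - m)] <- 1
    vol <- image_volume(img, spacing = cfg$spacing, mask = mask)
    attr(vol, "vessel_label") <- vessel_lab
    attr(vol, "diaphragm_label") <- diaphragm_lab
    vol
  })
}

# draw a slicing pose whose slice keeps at least `min_overlap` valid pixels
draw_true_pose <- function(volume, slice_shape, slice_spacing,
                           min_overlap = 0.5, max_tries = 100) {
  ext <- dim(volume$intensities) * volume$spacing
  for (i in seq_len(max_tries)) {
    R <- euler_to_rot(runif(1, -10, 10), runif(1, -10, 10), runif(1, -10, 10))
    t <- c(runif(1, -0.1, 0.1) * ext[1], runif(1, -0.1, 0.1) * ext[2],
           runif(1, -0.2, 0.2) * ext[3])
    T <- rigid_transform(R, t, validate = FALSE)
    sl <- suppressWarnings(extract_slice(volume, T, slice_shape, slice_spacing))
    if (mean(sl$mask) >= min_overlap) return(T)
  }
  stop("could not find a slicing pose with sufficient overlap in ", max_tries, " draws")
}

#' Generate a synthetic 2D-3D registration pair with ground truth
#'
#' Draws an exact slicing pose `theta_true` (uniform within an envelope that
#' keeps at least `min_overlap` of the slice inside the volume mask;
#' low-overlap draws are rejected and redrawn), extracts the reference
#' slice, and perturbs the pose with a tracking-error draw to produce the
#' tracked pose: `theta_tracked = theta_true o P`, so the ground-truth
#' correction is `delta_gt = P^-1` and
#' `compose(theta_tracked, delta_gt) = theta_true` exactly.
#'
#' @param volume an `image_volume` (typically from [generate_phantom()]).
#' @param slice_shape output slice size in pixels (length 2).
#' @param rng_seed integer seed for the pose draws.
#' @param perturb an [euler_perturbation()], or `NULL` to sample one from
#'   the augmentation distribution ([sample_perturbation()]).
#' @param perturb_scale range multiplier when sampling the perturbation.
#' @param slice_spacing pixel spacing of the reference slice (defaults to
#'   the volume's in-plane spacing).
#' @param noise_sd additive Gaussian noise applied to the reference slice
#'   only (default 0: the slice is the exact extraction).
#' @param min_overlap minimum fraction of valid slice pixels.
#' @return list of class `synthetic_pair` with fields `volume`, `ref_slice`,
#'   `theta_true`, `theta_tracked`, `delta_gt`, `perturb`, `seed`.
#' @export
make_pair <- function(volume, slice_shape = c(64, 64), rng_seed = 1,
                      perturb = NULL, perturb_scale = 1,
                      slice_spacing = volume$spacing[1:2], noise_sd = 0,
                      min_overlap = 0.5) {
  with_seed(rng_seed, {
    theta_true <- draw_true_pose(volume, slice_shape, slice_spacing, min_overlap)
    ref <- extract_slice(volume, theta_true, slice_shape, slice_spacing)
    if (noise_sd > 0) {
      ref$intensities <- pmin(pmax(ref$intensities +
        matrix(rnorm(length(ref$intensities), sd = noise_sd),
               nrow(ref$intensities)), 0), 1)
    }
    if (is.null(perturb)) perturb <- sample_perturbation(scale = perturb_scale)
    P <- perturbation_to_transform(perturb)
    theta_tracked <- compose(theta_true, P)
    delta_gt <- invert(P)
    structure(list(volume = volume, ref_slice = ref, theta_true = theta_true,
                   theta_tracked = theta_tracked, delta_gt = delta_gt,
                   perturb = perturb, seed = rng_seed),
              class = "synthetic_pair")
  })
}

#' Generate a synthetic frame sequence with smooth motion
#'
#' Emulates continuous organ (breathing-like) motion: the true slicing pose
#' follows a smooth sinusoidal rigid trajectory around a base pose, while
#' the tracked pose stays at the base pose plus small independent per-frame
#' jitter -- i.e. the tracker does not see the organ motion, which is
#' exactly the situation the temporal correction workflow addresses.
#'
#' @param volume an `image_volume`.
#' @param n_frames number of frames (>= 2).
#' @param amplitude_mm,amplitude_deg motion amplitudes.
#' @param period frames per motion cycle.
#' @param jitter_scale scale of the independent tracking jitter, as a
#'   fraction of the augmentation ranges (see [sample_perturbation()]).
#' @param slice_shape,slice_spacing reference slice geometry.
#' @param seed integer master seed.
#' @return list of class `synthetic_sequence`: fields `frames` (list of
#'   per-frame lists with `ref_slice`, `theta_tracked`, `theta_true`,
#'   `delta_gt`, `index`) plus the generation parameters. The frame-to-frame
#'   true-pose translation change is bounded by
#'   `amplitude_mm * 2 * pi / period` by construction.
#' @export
make_sequence <- function(volume, n_frames = 20, amplitude_mm = 5,
                          amplitude_deg = 2, period = 20, jitter_scale = 0.1,
                          slice_shape = c(64, 64),
                          slice_spacing = volume$spacing[1:2], seed = 1) {
  stopifnot(n_frames >= 2)
  with_seed(seed, {
    base <- draw_true_pose(volume, slice_shape, slice_spacing)
    phase <- runif(6, 0, 2 * pi)
    wt <- c(1, 0.7, 0.5)   # per-axis translation weights
    wr <- c(0.6, 0.6, 1)   # per-axis rotation weights
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      s <- sin(2 * pi * (f - 1) / period + phase)
      drift <- perturbation_to_transform(euler_perturbation(
        tx = amplitude_mm * wt[1] * s[1], ty = amplitude_mm * wt[2] * s[2],
        tz = amplitude_mm * wt[3] * s[3], rx = amplitude_deg * wr[1] * s[4],
        ry = amplitude_deg * wr[2] * s[5], rz = amplitude_deg * wr[3] * s[6]))
      theta_true <- compose(base, drift)
      jitter <- perturbation_to_transform(sample_perturbation(scale = jitter_scale))
      theta_tracked <- compose(base, jitter)
      delta_gt <- compose(invert(theta_tracked), theta_true)
      ref <- suppressWarnings(extract_slice(volume, theta_true, slice_shape, slice_spacing))
      frames[[f]] <- list(ref_slice = ref, theta_tracked = theta_tracked,
                          theta_true = theta_true, delta_gt = delta_gt,
                          index = f)
    }
    structure(list(frames = frames, volume = volume,
                   amplitude_mm = amplitude_mm, amplitude_deg = amplitude_deg,
                   period = period, seed = seed),
              class = "synthetic_sequence")
  })
}

#' Preprocess an image to the standard lattice
#'
#' Resamples isotropically to `target_spacing` (default 0.5 mm), center-crops
#' (or zero-pads) to `target_shape` -- defaults 400 x 320 pixels for slices
#' and 400 x 320 x 240 voxels for volumes -- and linearly rescales the
#' intensities to `[0, 1]` by the per-image min-max. The validity mask is
#' transported with the same resampling and re-binarized; padded regions are
#' masked out. The operation is idempotent.
#'
#' @param image an `image_volume` or `image_slice`.
#' @param target_spacing output spacing in mm.
#' @param target_shape output grid size; `NULL` uses the defaults above.
#' @return object of the same class as the input.
#' @export
preprocess <- function(image, target_spacing = 0.5, target_shape = NULL) {
  if (target_spacing <= 0) stop("target_spacing must be positive")
  if (inherits(image, "image_volume")) {
    if (is.null(target_shape)) target_shape <- c(400, 320, 240)
    stopifnot(length(target_shape) == 3)
    d <- as.integer(target_shape)
    ax <- lapply(1:3, function(a) ((seq_len(d[a]) - 1) - (d[a] - 1) / 2) * target_spacing)
    pts <- cbind(rep(ax[[1]], times = d[2] * d[3]),
                 rep(rep(ax[[2]], each = d[1]), times = d[3]),
                 rep(ax[[3]], each = d[1] * d[2]))
    res <- interpolate(image, pts)
    img <- array(res$value, d)
    msk <- array(res$mask, d)
    img <- rescale01(img)
    image_volume(img, spacing = target_spacing,
                 origin = volume_center(image) - (d - 1) / 2 * target_spacing,
                 mask = msk)
  } else if (inherits(image, "image_slice")) {
    if (is.null(target_shape)) target_shape <- c(400, 320)
    stopifnot(length(target_shape) == 2)
    d <- as.integer(target_shape)
    # treat the slice as a one-voxel-thick volume and sample its z = 0 plane
    vol <- image_volume(array(image$intensities, c(dim(image$intensities), 1)),
                        spacing = c(image$spacing, 1),
                        mask = array(image$mask, c(dim(image$mask), 1)))
    xs <- ((seq_len(d[1]) - 1) - (d[1] - 1) / 2) * target_spacing
    ys <- ((seq_len(d[2]) - 1) - (d[2] - 1) / 2) * target_spacing
    pts <- cbind(rep(xs, times = d[2]), rep(ys, each = d[1]), 0)
    res <- interpolate(vol, pts)
    img <- rescale01(matrix(res$value, d[1], d[2]))
    image_slice(img, spacing = target_spacing,
                mask = matrix(res$mask, d[1], d[2]))
  } else {
    stop("preprocess expects an image_volume or image_slice")
  }
}

rescale01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi > lo) (x - lo) / (hi - lo) else x * 0
}

#' Perturbed candidate poses around a registration result
#'
#' Generates `n` candidate poses by composing a registered pose with random
#' perturbations drawn as Normal(0, `sd_trans`) mm on each translation axis
#' and Normal(0, `sd_rot`) degrees on each Euler angle (defaults 1 mm and
#' 1.5 degrees; 100 candidates). Intended for building evaluation fixtures;
#' see [rank_candidates()] for the LNCC-based selection proxy.
#'
#' @param T_reg the registered `rigid_transform`.
#' @param n number of candidates (default 100).
#' @param seed integer seed.
#' @param sd_trans,sd_rot noise scales (mm, degrees).
#' @return list of `rigid_transform`s of length `n`.
#' @export
candidate_poses <- function(T_reg, n = 100, seed = 1, sd_trans = 1, sd_rot = 1.5) {
  stopifnot(n >= 1)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      p <- euler_perturbation(tx = rnorm(1, 0, sd_trans), ty = rnorm(1, 0, sd_trans),
                              tz = rnorm(1, 0, sd_trans), rx = rnorm(1, 0, sd_rot),
                              ry = rnorm(1, 0, sd_rot), rz = rnorm(1, 0, sd_rot))
      compose(T_reg, perturbation_to_transform(p, center = T_reg$center))
    })
  })
}

#' Rank candidate poses by masked LNCC
#'
#' Scores each candidate pose by the masked LNCC between the slice it
#' extracts and the reference. This is an automated proxy for the human
#' visual selection used with clinical data; on synthetic phantoms the
#' exact ground-truth pose is available and should be preferred.
#'
#' @param volume an `image_volume`.
#' @param ref an `image_slice` reference.
#' @param candidates list of `rigid_transform`s.
#' @param cfg a [similarity_config()].
#' @return list with `scores` (numeric), `best` (index), `best_pose`.
#' @export
rank_candidates <- function(volume, ref, candidates, cfg = similarity_config()) {
  scores <- vapply(candidates, function(T) {
    sl <- suppressWarnings(extract_slice(volume, T, dim(ref$intensities), ref$spacing))
    tryCatch(lncc_masked(sl, ref, cfg), slicereg_overlap_error = function(e) -Inf)
  }, numeric(1))
  best <- which.max(scores)
  list(scores = scores, best = best, best_pose = candidates[[best]])
}
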