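# Convenience builders for registration experiments: turning phantoms into
# network-ready training/evaluation sets.

#' Build a network training set from phantom volumes
#'
#' Draws `n_pairs` synthetic pairs (cycling over the supplied volumes),
#' applies each pair's tracked transform to its volume (the composed
#' initial transform of the temporal workflow, with no previous correction),
#' and packages the samples in the structure [train_network()] consumes.
#'
#' @param volumes list of `image_volume`s (e.g. from [generate_phantom()]).
#' @param n_pairs number of samples.
#' @param slice_shape reference slice size in pixels.
#' @param seed integer; pair `i` uses seed `seed + i`.
#' @param perturb_scale augmentation range multiplier (see
#'   [sample_perturbation()]).
#' @return list of samples, each with `vol_init`, `ref`, `delta_gt`, and
#'   `pair` (the full `synthetic_pair`, volume omitted to save memory).
#' @export
make_registration_dataset <- function(volumes, n_pairs, slice_shape = c(64, 64),
                                      seed = 1, perturb_scale = 1) {
  if (inherits(volumes, "image_volume")) volumes <- list(volumes)
  lapply(seq_len(n_pairs), function(i) {
    vol <- volumes[[(i - 1) %% length(volumes) + 1]]
    pr <- make_pair(vol, slice_shape = slice_shape, rng_seed = seed + i,
                    perturb_scale = perturb_scale)
    vol_init <- transform_volume(vol, pr$theta_tracked)
    pr$volume <- NULL
    list(vol_init = vol_init, ref = pr$ref_slice, delta_gt = pr$delta_gt,
         pair = pr)
  })
}

#' Evaluate predicted corrections on a dataset
#'
#' For every sample, compares the network's predicted correction with the
#' ground truth and with the uncorrected (identity) initialization.
#'
#' @param dataset samples from [make_registration_dataset()].
#' @param weights trained `network_weights`.
#' @param cfg the matching [network_config()].
#' @return `data.frame` with per-sample `ed_pred`, `ga_pred`, `ed_init`,
#'   `ga_init`.
#' @export
evaluate_predictions <- function(dataset, weights, cfg) {
  rows <- lapply(dataset, function(smp) {
    dp <- predict_correction(smp$vol_init, smp$ref, weights, cfg)
    pe <- pose_error(dp, smp$delta_gt)
    pe0 <- pose_error(identity_transform(), smp$delta_gt)
    data.frame(ed_pred = pe$ed, ga_pred = pe$ga,
               ed_init = pe0$ed, ga_init = pe0$ga)
  })
  do.call(rbind, rows)
}
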