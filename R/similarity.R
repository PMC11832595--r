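# Similarity metrics: masked-intersection local normalized cross-correlation
# (LNCC), global NCC, and the combined registration training loss.
#
# The LNCC is computed on windows centered at every pixel, restricted to the
# joint validity mask (mask-weighted means/variances). "Window area" is the
# number of in-image pixels of the boundary-clipped window, so that windows
# at the image edge and windows larger than the image are treated
# consistently; a window contributes only if at least half its area is
# inside the joint mask. This realizes the metric "on the intersection" of
# the two images for arbitrary (rectangular or polygonal) intersections.

#' Similarity configuration
#'
#' @param kernel_size odd LNCC window width in pixels (default 51).
#' @param epsilon variance floor inside the correlation denominator; windows
#'   with (mask-weighted) variance below `epsilon` are treated as flat.
#' @param min_overlap_fraction minimum joint-mask size, as a fraction of the
#'   smaller of the two input masks, below which the metric is declared
#'   unreliable and an error of class `slicereg_overlap_error` is raised.
#' @return list of class `similarity_config`.
#' @export
similarity_config <- function(kernel_size = 51, epsilon = 1e-5,
                              min_overlap_fraction = 0.05) {
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 3 || kernel_size %% 2 == 0) {
    stop("kernel_size must be an odd integer >= 3")
  }
  if (epsilon <= 0) stop("epsilon must be positive")
  if (min_overlap_fraction <= 0 || min_overlap_fraction > 1) {
    stop("min_overlap_fraction must be in (0, 1]")
  }
  structure(list(kernel_size = kernel_size, epsilon = epsilon,
                 min_overlap_fraction = min_overlap_fraction),
            class = "similarity_config")
}

overlap_error <- function(msg) {
  stop(structure(class = c("slicereg_overlap_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_overlap <- function(m, ma, mb, min_fraction) {
  ref <- min(sum(ma), sum(mb))
  if (ref == 0 || sum(m) < min_fraction * ref) {
    overlap_error(sprintf(
      "insufficient mask overlap (%d joint pixels, %.1f%% of the reference mask)",
      sum(m), if (ref > 0) 100 * sum(m) / ref else 0))
  }
}

as_slice_pair <- function(a, b) {
  stopifnot(inherits(a, "image_slice"), inherits(b, "image_slice"))
  if (!identical(dim(a$intensities), dim(b$intensities))) {
    stop("slices must have the same shape")
  }
  invisible(NULL)
}

# Windowed mask-weighted statistics shared by the LNCC forward and backward
# passes. Returns per-pixel-centered window quantities.
lncc_stats <- function(a, b, m, k, eps) {
  n <- .box_sum_cpp(m, k)
  area <- .box_sum_cpp(array(1, dim(m)), k)
  sa <- .box_sum_cpp(m * a, k)
  sb <- .box_sum_cpp(m * b, k)
  saa <- .box_sum_cpp(m * a * a, k)
  sbb <- .box_sum_cpp(m * b * b, k)
  sab <- .box_sum_cpp(m * a * b, k)
  pos <- n > 0
  abar <- ifelse(pos, sa / pmax(n, 1), 0)
  bbar <- ifelse(pos, sb / pmax(n, 1), 0)
  cov <- sab - n * abar * bbar
  va <- pmax(saa - n * abar^2, 0)
  vb <- pmax(sbb - n * bbar^2, 0)
  valid <- pos & (n >= area / 2)
  ncc <- cov / sqrt(pmax(va, eps) * pmax(vb, eps))
  list(n = n, abar = abar, bbar = bbar, cov = cov, va = va, vb = vb,
       valid = valid, ncc = ncc)
}

#' Masked local normalized cross-correlation
#'
#' Windowed NCC restricted to the intersection of the two validity masks,
#' averaged over all windows with at least half their (in-image) area inside
#' the joint mask. Bounded in `[-1, 1]`, symmetric in its image arguments,
#' invariant to positive affine intensity maps and to any content outside
#' the joint mask.
#'
#' @param a,b `image_slice` objects of equal shape.
#' @param cfg a [similarity_config()].
#' @param backward also return the gradient of the metric with respect to
#'   the intensities of `a` (only inside the joint mask).
#' @return the LNCC value, or (with `backward = TRUE`) a list
#'   `list(value, grad_a)`.
#' @export
lncc_masked <- function(a, b, cfg = similarity_config(), backward = FALSE) {
  as_slice_pair(a, b)
  m <- a$mask * b$mask
  check_overlap(m, a$mask, b$mask, cfg$min_overlap_fraction)
  k <- cfg$kernel_size
  eps <- cfg$epsilon
  st <- lncc_stats(a$intensities, b$intensities, m, k, eps)
  if (!any(st$valid)) {
    overlap_error("no LNCC window reaches half-area mask occupancy")
  }
  value <- mean(st$ncc[st$valid])
  if (!backward) return(value)
  nv <- sum(st$valid)
  vas <- pmax(st$va, eps)
  vbs <- pmax(st$vb, eps)
  P <- ifelse(st$valid, 1 / sqrt(vas * vbs), 0)
  Q <- ifelse(st$valid & (st$va > eps), st$cov / (vas^1.5 * sqrt(vbs)), 0)
  bp <- .box_sum_cpp(P, k)
  bpb <- .box_sum_cpp(P * st$bbar, k)
  bq <- .box_sum_cpp(Q, k)
  bqa <- .box_sum_cpp(Q * st$abar, k)
  grad_a <- m * (b$intensities * bp - bpb - a$intensities * bq + bqa) / nv
  list(value = value, grad_a = grad_a)
}

#' Global normalized cross-correlation
#'
#' Single NCC over all pixels of the joint validity mask.
#'
#' @param a,b `image_slice` objects of equal shape.
#' @param epsilon variance floor (as in [similarity_config()]).
#' @return value in `[-1, 1]`.
#' @export
gncc <- function(a, b, epsilon = 1e-5) {
  as_slice_pair(a, b)
  m <- (a$mask * b$mask) > 0
  if (!any(m)) overlap_error("empty joint mask")
  x <- a$intensities[m]
  y <- b$intensities[m]
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(max(sum(xc^2), epsilon) * max(sum(yc^2), epsilon))
}

#' Combined registration loss
#'
#' The training loss `alpha * (1 - LNCC) + beta * ||t_pred - t_gt||^2 +
#' gamma * GeoErr(R_pred, R_gt)`, with the translation term in mm^2 and the
#' geodesic term in radians. The image term uses the masked-intersection
#' LNCC of the predicted versus reference slice; at a perfect prediction
#' with identical images the loss is 0.
#'
#' @param pred_slice,ref_slice `image_slice` objects of equal shape.
#' @param pred_pose,gt_pose `rigid_transform` corrections.
#' @param w a [loss_weights()] object.
#' @param cfg a [similarity_config()].
#' @return list with `total` and a per-term breakdown
#'   (`lncc`, `loss_image`, `loss_trans`, `loss_rot`).
#' @export
combined_loss <- function(pred_slice, ref_slice, pred_pose, gt_pose,
                          w = loss_weights(), cfg = similarity_config()) {
  stopifnot(inherits(w, "loss_weights"))
  lncc <- lncc_masked(pred_slice, ref_slice, cfg)
  loss_image <- 1 - lncc
  dtr <- pred_pose$translation - gt_pose$translation
  loss_trans <- sum(dtr^2)
  loss_rot <- geodesic_error(pred_pose$rotation, gt_pose$rotation, degrees = FALSE)
  list(total = w$alpha * loss_image + w$beta * loss_trans + w$gamma * loss_rot,
       lncc = lncc, loss_image = loss_image, loss_trans = loss_trans,
       loss_rot = loss_rot)
}
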