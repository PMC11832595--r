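# The pose regression network: a 2D encoder for the reference frame, a 3D
# encoder for the initially transformed volume, a parameter-free dot-product
# (outer-product) feature fusion producing a fused "volume", a 3D decoder
# and a fully-connected head emitting 9 numbers (6D rotation + translation).
# Forward and backward passes are implemented explicitly on top of the
# package's im2col convolution kernels; the rotation head goes through the
# Gram-Schmidt map so every emitted rotation is exactly orthonormal.

#' Network configuration
#'
#' Architecture and training hyperparameters. The training defaults mirror
#' the reference schedule (Adam, starting learning rate 1e-6 decayed by 0.8
#' every 80 epochs, batch size 2); the architecture defaults are the
#' smallest configuration that preserves the fusion topology and trains at
#' desk scale on CPU.
#'
#' @param input_shape_3d,input_shape_2d expected input grids.
#' @param encoder_stages_3d,encoder_stages_2d number of stride-2
#'   convolution stages (kernel 3, padding 1, ReLU).
#' @param base_channels channels of the first stage; stage `s` has
#'   `base_channels * 2^(s-1)`.
#' @param fused_feature_shape dimensions `(i, j, k)` of the fused feature
#'   volume: the 3D features are projected to an `i x j` matrix, the 2D
#'   features to a length-`k` vector, and fusion forms their outer product.
#' @param decoder_channels channels of the 3D decoder stages.
#' @param fc_hidden width of the hidden fully-connected layer.
#' @param seed master seed; fans out to weight init and data order.
#' @param learning_rate,lr_gamma,lr_step_epochs step-decay Adam schedule.
#' @param batch_size,epochs training loop defaults.
#' @return list of class `network_config`.
#' @export
network_config <- function(input_shape_3d = c(64, 64, 64),
                           input_shape_2d = c(64, 64),
                           encoder_stages_3d = 4, encoder_stages_2d = 4,
                           base_channels = 8,
                           fused_feature_shape = c(16, 16, 64),
                           decoder_channels = c(8, 16, 32),
                           fc_hidden = 64, seed = 1,
                           learning_rate = 1e-6, lr_gamma = 0.8,
                           lr_step_epochs = 80, batch_size = 2,
                           epochs = 1200) {
  stopifnot(encoder_stages_3d >= 1, encoder_stages_2d >= 1,
            base_channels >= 1, length(fused_feature_shape) == 3,
            all(fused_feature_shape >= 1), fc_hidden >= 1,
            learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(input_shape_3d = as.integer(input_shape_3d),
                 input_shape_2d = as.integer(input_shape_2d),
                 encoder_stages_3d = as.integer(encoder_stages_3d),
                 encoder_stages_2d = as.integer(encoder_stages_2d),
                 base_channels = as.integer(base_channels),
                 fused_feature_shape = as.integer(fused_feature_shape),
                 decoder_channels = as.integer(decoder_channels),
                 fc_hidden = as.integer(fc_hidden), seed = seed,
                 learning_rate = learning_rate, lr_gamma = lr_gamma,
                 lr_step_epochs = lr_step_epochs,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs)),
            class = "network_config")
}

conv_out_shape <- function(n, stages) {
  for (s in seq_len(stages)) n <- (n + 2 - 3) %/% 2 + 1
  n
}

stage_channels <- function(cfg, stages) cfg$base_channels * 2^(seq_len(stages) - 1)

#' Initialize network weights
#'
#' He initialization for the convolution stacks and hidden layer, Xavier
#' for the linear feature projections. The final head starts near the
#' identity pose: its weights are drawn at scale 1e-3 and its bias is the
#' 6D identity rotation `(1,0,0, 0,1,0)` with zero translation, so an
#' untrained network predicts (near-)identity corrections.
#'
#' @param cfg a [network_config()].
#' @return nested list of weight arrays (class `network_weights`).
#' @export
init_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  with_seed(cfg$seed, {
    conv_stage <- function(k3, cin, cout) {
      kd <- if (k3) c(3, 3, 3) else c(3, 3, 1)
      fan_in <- prod(kd) * cin
      list(W = array(rnorm(prod(kd) * cin * cout, sd = sqrt(2 / fan_in)),
                     c(kd, cin, cout)),
           b = rep(0, cout))
    }
    fc_layer <- function(nin, nout, sd = sqrt(1 / nin), bias = rep(0, nout)) {
      list(W = matrix(rnorm(nin * nout, sd = sd), nin, nout), b = bias)
    }
    ch2 <- stage_channels(cfg, cfg$encoder_stages_2d)
    ch3 <- stage_channels(cfg, cfg$encoder_stages_3d)
    enc2d <- lapply(seq_along(ch2), function(s) {
      conv_stage(FALSE, if (s == 1) 1 else ch2[s - 1], ch2[s])
    })
    enc3d <- lapply(seq_along(ch3), function(s) {
      conv_stage(TRUE, if (s == 1) 1 else ch3[s - 1], ch3[s])
    })
    flat2 <- prod(sapply(cfg$input_shape_2d, conv_out_shape,
                         stages = cfg$encoder_stages_2d)) * ch2[length(ch2)]
    flat3 <- prod(sapply(cfg$input_shape_3d, conv_out_shape,
                         stages = cfg$encoder_stages_3d)) * ch3[length(ch3)]
    fshape <- cfg$fused_feature_shape
    dec_in <- fshape
    dch <- cfg$decoder_channels
    dec <- lapply(seq_along(dch), function(s) {
      conv_stage(TRUE, if (s == 1) 1 else dch[s - 1], dch[s])
    })
    dec_spatial <- sapply(dec_in, conv_out_shape, stages = length(dch))
    flat_dec <- prod(dec_spatial) * dch[length(dch)]
    structure(list(
      enc2d = enc2d,
      enc3d = enc3d,
      proj2d = fc_layer(flat2, fshape[3]),
      proj3d = fc_layer(flat3, fshape[1] * fshape[2]),
      dec = dec,
      fc1 = fc_layer(flat_dec, cfg$fc_hidden, sd = sqrt(2 / flat_dec)),
      fc2 = fc_layer(cfg$fc_hidden, 9, sd = 1e-3,
                     bias = c(1, 0, 0, 0, 1, 0, 0, 0, 0))
    ), class = "network_weights")
  })
}

#' Number of trainable parameters
#' @param weights a `network_weights` object.
#' @return integer parameter count (the fusion layer contributes none).
#' @export
n_parameters <- function(weights) {
  length(unlist(weights, use.names = FALSE))
}

relu <- function(x) { x[x < 0] <- 0; x }

conv_stack_fwd <- function(x, stages, pad) {
  cache <- vector("list", length(stages))
  for (s in seq_along(stages)) {
    pre <- .conv3d_fwd_cpp(x, stages[[s]]$W, stages[[s]]$b, 2L, as.integer(pad))
    out <- relu(pre)
    cache[[s]] <- list(input = x, pre = pre)
    x <- out
  }
  list(out = x, cache = cache)
}

conv_stack_bwd <- function(g, stages, cache, pad, need_input_grad = FALSE) {
  grads <- vector("list", length(stages))
  for (s in rev(seq_along(stages))) {
    g <- g * (cache[[s]]$pre > 0)
    need <- need_input_grad || s > 1
    bw <- .conv3d_bwd_cpp(g, cache[[s]]$input, stages[[s]]$W, 2L,
                          as.integer(pad), need)
    grads[[s]] <- list(W = bw$grad_w, b = bw$grad_b)
    if (need) g <- bw$grad_in else g <- NULL
  }
  list(grads = grads, grad_in = g)
}

fc_fwd <- function(x, layer) as.numeric(x %*% layer$W) + layer$b

#' Encode the 2D reference frame
#'
#' Stride-2 convolutional downsampling of the 2D slice followed by a linear
#' projection to the fused feature length `k`.
#'
#' @param slice an `image_slice` (or bare matrix) of the configured size.
#' @param weights a `network_weights` object.
#' @param cfg the matching [network_config()].
#' @return numeric feature vector of length `cfg$fused_feature_shape[3]`.
#' @export
encode_2d <- function(slice, weights, cfg) {
  m <- if (inherits(slice, "image_slice")) slice$intensities else slice
  if (!identical(dim(m), as.integer(cfg$input_shape_2d))) {
    stop("2D input shape does not match the network configuration")
  }
  x <- array(m, c(dim(m), 1, 1))
  enc <- conv_stack_fwd(x, weights$enc2d, c(1, 1, 0))
  fc_fwd(as.numeric(enc$out), weights$proj2d)
}

#' Encode the (initially transformed) 3D volume
#'
#' Stride-2 convolutional downsampling of the volume followed by a linear
#' projection, reshaped to the `i x j` fused feature matrix. The volume is
#' expected to carry the composed initial transform already (the previous
#' correction enters the network only through this resampling).
#'
#' @param volume an `image_volume` (or bare 3D array) of the configured size.
#' @param weights a `network_weights` object.
#' @param cfg the matching [network_config()].
#' @return matrix of dimension `cfg$fused_feature_shape[1:2]`.
#' @export
encode_3d <- function(volume, weights, cfg) {
  a <- if (inherits(volume, "image_volume")) volume$intensities else volume
  if (!identical(dim(a), as.integer(cfg$input_shape_3d))) {
    stop("3D input shape does not match the network configuration")
  }
  x <- array(a, c(dim(a), 1))
  enc <- conv_stack_fwd(x, weights$enc3d, c(1, 1, 1))
  f <- fc_fwd(as.numeric(enc$out), weights$proj3d)
  matrix(f, cfg$fused_feature_shape[1], cfg$fused_feature_shape[2])
}

#' Dot-product feature fusion
#'
#' Parameter-free fusion of the 3D feature matrix and the 2D feature
#' vector: `fmerged[i, j, k] = f3d[i, j] * f2d[k]`, an outer product whose
#' result is treated as a volume by the decoder. Balances the contribution
#' of the two inputs and correlates every 3D feature with every 2D feature.
#'
#' @param f3d numeric matrix.
#' @param f2d numeric vector.
#' @return 3D array of dimension `c(dim(f3d), length(f2d))`.
#' @export
fuse_dot_product <- function(f3d, f2d) {
  stopifnot(all(is.finite(f3d)), all(is.finite(f2d)))
  outer(as.matrix(f3d), as.numeric(f2d))
}

#' Decode the fused feature volume to a pose
#'
#' 3D convolutional downsampling of the fused volume plus a two-layer
#' fully-connected head emitting 9 numbers: a 6D rotation and a translation
#' (mm, center-relative). The rotation passes through the Gram-Schmidt map,
#' so it is orthonormal by construction; a degenerate head output falls
#' back to the identity rotation with a warning.
#'
#' @param fmerged fused volume from [fuse_dot_product()].
#' @param weights a `network_weights` object.
#' @param cfg the matching [network_config()].
#' @return list of class `pose_vector` with fields `r6` (length 6), `t`
#'   (length 3, mm).
#' @export
decode_pose <- function(fmerged, weights, cfg) {
  if (!identical(dim(fmerged), as.integer(cfg$fused_feature_shape))) {
    stop("fused feature shape does not match the network configuration")
  }
  x <- array(fmerged, c(dim(fmerged), 1))
  dec <- conv_stack_fwd(x, weights$dec, c(1, 1, 1))
  h <- relu(fc_fwd(as.numeric(dec$out), weights$fc1))
  out <- fc_fwd(h, weights$fc2)
  structure(list(r6 = out[1:6], t = out[7:9]), class = "pose_vector")
}

#' Convert a pose vector to a rigid transform
#'
#' @param pv a `pose_vector`.
#' @param center rotation center (mm).
#' @return a `rigid_transform`; a degenerate 6D rotation part falls back to
#'   the identity rotation with a warning.
#' @export
pose_to_transform <- function(pv, center = c(0, 0, 0)) {
  R <- tryCatch(sixd_to_rot(pv$r6), error = function(e) {
    warning("degenerate 6D rotation output; falling back to identity rotation")
    diag(3)
  })
  rigid_transform(R, pv$t, center = center, validate = FALSE)
}

# Full forward pass with caches for the backward pass.
net_forward <- function(vol_arr, slice_arr, weights, cfg) {
  x3 <- array(vol_arr, c(dim(vol_arr), 1))
  x2 <- array(slice_arr, c(dim(slice_arr), 1, 1))
  e3 <- conv_stack_fwd(x3, weights$enc3d, c(1, 1, 1))
  e2 <- conv_stack_fwd(x2, weights$enc2d, c(1, 1, 0))
  flat3 <- as.numeric(e3$out)
  flat2 <- as.numeric(e2$out)
  f3d <- matrix(fc_fwd(flat3, weights$proj3d),
                cfg$fused_feature_shape[1], cfg$fused_feature_shape[2])
  f2d <- fc_fwd(flat2, weights$proj2d)
  fused <- outer(f3d, f2d)
  xd <- array(fused, c(dim(fused), 1))
  dc <- conv_stack_fwd(xd, weights$dec, c(1, 1, 1))
  flatd <- as.numeric(dc$out)
  h_pre <- fc_fwd(flatd, weights$fc1)
  h <- relu(h_pre)
  out <- fc_fwd(h, weights$fc2)
  list(out = out,
       cache = list(e3 = e3, e2 = e2, flat3 = flat3, flat2 = flat2,
                    f3d = f3d, f2d = f2d, dc = dc, flatd = flatd,
                    h_pre = h_pre, h = h))
}

net_backward <- function(g_out, weights, cache, cfg) {
  gW2 <- outer(cache$h, g_out)
  gb2 <- g_out
  gh <- as.numeric(weights$fc2$W %*% g_out) * (cache$h_pre > 0)
  gW1 <- outer(cache$flatd, gh)
  gb1 <- gh
  gflatd <- as.numeric(weights$fc1$W %*% gh)
  gdec_out <- array(gflatd, dim(cache$dc$cache[[length(weights$dec)]]$pre))
  dec_bw <- conv_stack_bwd(gdec_out, weights$dec, cache$dc$cache, c(1, 1, 1),
                           need_input_grad = TRUE)
  gfused <- array(dec_bw$grad_in, dim = c(dim(cache$f3d), length(cache$f2d)))
  # fusion backward: outer-product chain rule
  k <- length(cache$f2d)
  gf3d <- matrix(0, nrow(cache$f3d), ncol(cache$f3d))
  gf2d <- numeric(k)
  for (kk in seq_len(k)) {
    gk <- gfused[, , kk]
    gf3d <- gf3d + gk * cache$f2d[kk]
    gf2d[kk] <- sum(gk * cache$f3d)
  }
  gP3W <- outer(cache$flat3, as.numeric(gf3d))
  gP3b <- as.numeric(gf3d)
  gflat3 <- as.numeric(weights$proj3d$W %*% as.numeric(gf3d))
  gP2W <- outer(cache$flat2, gf2d)
  gP2b <- gf2d
  gflat2 <- as.numeric(weights$proj2d$W %*% gf2d)
  ge3 <- array(gflat3, dim(cache$e3$cache[[length(weights$enc3d)]]$pre))
  ge2 <- array(gflat2, dim(cache$e2$cache[[length(weights$enc2d)]]$pre))
  e3_bw <- conv_stack_bwd(ge3, weights$enc3d, cache$e3$cache, c(1, 1, 1))
  e2_bw <- conv_stack_bwd(ge2, weights$enc2d, cache$e2$cache, c(1, 1, 0))
  structure(list(enc2d = e2_bw$grads, enc3d = e3_bw$grads,
                 proj2d = list(W = gP2W, b = gP2b),
                 proj3d = list(W = gP3W, b = gP3b),
                 dec = dec_bw$grads,
                 fc1 = list(W = gW1, b = gb1),
                 fc2 = list(W = gW2, b = gb2)),
            class = "network_weights")
}

#' Predict the correction transform for one frame
#'
#' Full forward pass (encode 2D, encode 3D, fuse, decode): returns the
#' predicted correction as a rigid transform about the volume center. The
#' volume must already carry the composed initial transform.
#'
#' @param vol_init the initially transformed `image_volume`.
#' @param ref the reference `image_slice`.
#' @param weights a `network_weights` object.
#' @param cfg the matching [network_config()].
#' @return a `rigid_transform`.
#' @export
predict_correction <- function(vol_init, ref, weights, cfg) {
  f3d <- encode_3d(vol_init, weights, cfg)
  f2d <- encode_2d(ref, weights, cfg)
  pv <- decode_pose(fuse_dot_product(f3d, f2d), weights, cfg)
  pose_to_transform(pv)
}

# flatten / unflatten parameter trees (for the Adam state)
flatten_params <- function(w) unlist(w, use.names = FALSE)

unflatten_params <- function(vec, skel) {
  idx <- 0
  rec <- function(node) {
    if (is.list(node)) return(lapply(node, rec))
    n <- length(node)
    out <- vec[(idx + 1):(idx + n)]
    idx <<- idx + n
    attributes(out) <- attributes(node)
    out
  }
  out <- rec(skel)
  class(out) <- class(skel)
  out
}

#' Train the pose regression network
#'
#' Per-sample pipeline: forward pass to a 9-number pose, extraction of the
#' predicted slice through the differentiable resampler, and the combined
#' loss `alpha (1 - LNCC) + beta ||t - t_gt||^2 + gamma GeoErr`; all three
#' terms are backpropagated to the network (the image term through the
#' analytic resampler/LNCC gradients). Optimized with Adam under a step
#' decay schedule. Samples whose predicted slice loses mask overlap
#' contribute only the supervised terms and are counted, not fatal.
#'
#' @param dataset list of samples, each a list with `vol_init` (an
#'   `image_volume` already carrying the composed initial transform), `ref`
#'   (an `image_slice`) and `delta_gt` (the ground-truth correction,
#'   a `rigid_transform`).
#' @param cfg a [network_config()].
#' @param w a [loss_weights()].
#' @param sim a [similarity_config()] for the image term.
#' @param weights optional starting weights (default fresh [init_network()]).
#' @param epochs,learning_rate,batch_size overrides of the config values.
#' @param use_image_term include the LNCC image term (default TRUE).
#' @param verbose print per-epoch losses.
#' @return list with `weights`, `history` (`data.frame` per epoch: total and
#'   per-term means), and `skipped` (image-term skips due to lost overlap).
#' @export
train_network <- function(dataset, cfg, w = loss_weights(),
                          sim = similarity_config(), weights = NULL,
                          epochs = cfg$epochs,
                          learning_rate = cfg$learning_rate,
                          batch_size = cfg$batch_size,
                          use_image_term = TRUE, verbose = FALSE) {
  stopifnot(length(dataset) >= 1)
  if (is.null(weights)) weights <- init_network(cfg)
  theta <- flatten_params(weights)
  m <- numeric(length(theta))
  v <- numeric(length(theta))
  tstep <- 0
  skipped <- 0
  hist <- vector("list", epochs)
  with_seed(cfg$seed + 1, {
    for (ep in seq_len(epochs)) {
      lr <- learning_rate * cfg$lr_gamma^((ep - 1) %/% cfg$lr_step_epochs)
      ord <- sample(length(dataset))
      ep_loss <- c(total = 0, image = 0, trans = 0, rot = 0)
      nb <- 0
      for (b0 in seq(1, length(ord), by = batch_size)) {
        batch <- ord[b0:min(b0 + batch_size - 1, length(ord))]
        gacc <- NULL
        bl <- c(total = 0, image = 0, trans = 0, rot = 0)
        for (s in batch) {
          smp <- dataset[[s]]
          fw <- net_forward(smp$vol_init$intensities, smp$ref$intensities,
                            weights, cfg)
          out <- fw$out
          v6 <- out[1:6]
          tr <- out[7:9]
          R <- sixd_to_rot(v6)
          tgt <- smp$delta_gt$translation
          Rgt <- smp$delta_gt$rotation
          loss_trans <- sum((tr - tgt)^2)
          loss_rot <- geodesic_error(R, Rgt, degrees = FALSE)
          g_t <- 2 * w$beta * (tr - tgt)
          g_R <- w$gamma * geodesic_grad(R, Rgt)
          loss_image <- 0
          if (use_image_term && w$alpha > 0) {
            T_pred <- rigid_transform(R, tr, validate = FALSE)
            pred <- slice_like(smp$vol_init, T_pred, smp$ref)
            lb <- tryCatch(lncc_masked(pred, smp$ref, sim, backward = TRUE),
                           slicereg_overlap_error = function(e) NULL)
            if (is.null(lb)) {
              skipped <- skipped + 1
            } else {
              loss_image <- 1 - lb$value
              spb <- slice_pose_backward(smp$vol_init, T_pred,
                                         -w$alpha * lb$grad_a, smp$ref$spacing)
              g_t <- g_t + spb$grad_t
              g_R <- g_R + spb$grad_R
            }
          }
          g_out <- c(as.numeric(crossprod(sixd_jacobian(v6), as.numeric(g_R))),
                     g_t)
          gr <- net_backward(g_out, weights, fw$cache, cfg)
          gvec <- flatten_params(gr)
          gacc <- if (is.null(gacc)) gvec else gacc + gvec
          bl <- bl + c(w$alpha * loss_image + w$beta * loss_trans +
                         w$gamma * loss_rot,
                       loss_image, loss_trans, loss_rot)
        }
        gacc <- gacc / length(batch)
        tstep <- tstep + 1
        m <- 0.9 * m + 0.1 * gacc
        v <- 0.999 * v + 0.001 * gacc^2
        mh <- m / (1 - 0.9^tstep)
        vh <- v / (1 - 0.999^tstep)
        theta <- theta - lr * mh / (sqrt(vh) + 1e-8)
        weights <- unflatten_params(theta, weights)
        ep_loss <- ep_loss + bl / length(batch)
        nb <- nb + 1
      }
      ep_loss <- ep_loss / nb
      hist[[ep]] <- data.frame(epoch = ep, lr = lr, total = ep_loss["total"],
                               image = ep_loss["image"], trans = ep_loss["trans"],
                               rot = ep_loss["rot"], row.names = NULL)
      if (verbose) {
        message(sprintf("epoch %3d  lr %.2e  loss %.4f (img %.3f  trans %.2f  rot %.3f)",
                        ep, lr, ep_loss["total"], ep_loss["image"],
                        ep_loss["trans"], ep_loss["rot"]))
      }
    }
  })
  list(weights = weights, history = do.call(rbind, hist), skipped = skipped)
}
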