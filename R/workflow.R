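# The temporal registration workflow: compose the tracked pose with the
# previous frame's correction, predict a correction with the regression
# network, optionally refine it by gradient ascent on the masked LNCC, and
# the classical global-NCC baseline registrar.

#' Frame observation
#'
#' One time point of a 2D sweep: the live reference slice and the pose
#' reported by the probe tracker (which is ignorant of internal organ
#' motion).
#'
#' @param ref_slice an `image_slice`.
#' @param theta_tracked the tracked `rigid_transform`.
#' @param index nonnegative integer time index.
#' @return list of class `frame_observation`.
#' @export
frame_observation <- function(ref_slice, theta_tracked, index = 0) {
  stopifnot(inherits(ref_slice, "image_slice"),
            inherits(theta_tracked, "rigid_transform"), index >= 0)
  structure(list(ref_slice = ref_slice, theta_tracked = theta_tracked,
                 index = as.integer(index)),
            class = "frame_observation")
}

#' Initial transform of a frame
#'
#' Composes the tracked pose with the previous frame's correction,
#' `T(theta_tracked) o T(delta_prev)`; feeding the previous correction
#' stabilizes the registration under smooth organ motion. For the first
#' frame `delta_prev` is the identity.
#'
#' @param theta_tracked tracked pose (`rigid_transform`).
#' @param delta_prev previous correction (`rigid_transform`).
#' @return a `rigid_transform`.
#' @export
initial_transform <- function(theta_tracked, delta_prev = identity_transform()) {
  compose(theta_tracked, delta_prev)
}

#' Refinement configuration
#'
#' Settings for the iterative similarity-ascent stages. Steps are applied to
#' normalized parameter-block gradients (rotation in 6D units, translation
#' in mm) and halved whenever a step fails to improve the similarity, so the
#' final precision is far below the initial step size.
#'
#' @param step_t initial translation step, mm.
#' @param step_r initial rotation step (6D units for [refine_correction()],
#'   degrees for [gncc_baseline()]).
#' @param max_iter iteration budget.
#' @param tol convergence: stop when both step sizes fall below `tol` times
#'   their initial values.
#' @param sim a [similarity_config()] for the LNCC objective.
#' @return list of class `refine_config`.
#' @export
refine_config <- function(step_t = 0.5, step_r = 0.02, max_iter = 200,
                          tol = 1e-3, sim = similarity_config()) {
  stopifnot(step_t > 0, step_r > 0, max_iter >= 1, tol > 0)
  structure(list(step_t = step_t, step_r = step_r, max_iter = max_iter,
                 tol = tol, sim = sim),
            class = "refine_config")
}

slice_like <- function(volume, T, ref) {
  suppressWarnings(extract_slice(volume, T, dim(ref$intensities), ref$spacing))
}

#' Refine a pose by gradient ascent on the masked LNCC
#'
#' Maximizes the masked-intersection LNCC between the extracted slice and
#' the reference over the 9 pose parameters (6D rotation + translation),
#' through the differentiable resampler, starting at `T_init`. Uses
#' normalized block gradients with step halving on non-improvement and
#' returns the best pose seen, so the similarity trace is nondecreasing.
#'
#' @param volume an `image_volume`.
#' @param ref reference `image_slice`.
#' @param T_init starting `rigid_transform`.
#' @param cfg a [refine_config()].
#' @return list with `transform` (best pose), `similarity` (its LNCC),
#'   `trace` (best-seen LNCC per iteration), `iterations`, `termination`
#'   (`"converged"`, `"max_iterations"`, or `"lost_overlap"`).
#' @export
refine_correction <- function(volume, ref, T_init, cfg = refine_config()) {
  v <- as_sixd_vec(rot_to_6d(T_init$rotation))
  tr <- T_init$translation
  ctr <- T_init$center
  eval_pose <- function(v, tr) {
    T <- rigid_transform(sixd_to_rot(v), tr, center = ctr, validate = FALSE)
    sl <- slice_like(volume, T, ref)
    list(T = T, slice = sl, lncc = lncc_masked(sl, ref, cfg$sim, backward = TRUE))
  }
  cur <- eval_pose(v, tr)   # overlap error at start propagates to the caller
  best <- list(v = v, tr = tr, value = cur$lncc$value)
  step_t <- cfg$step_t
  step_r <- cfg$step_r
  trace <- numeric(0)
  termination <- "max_iterations"
  lost <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    bk <- slice_pose_backward(volume, cur$T, cur$lncc$grad_a, ref$spacing)
    g_v <- as.numeric(crossprod(sixd_jacobian(v), as.numeric(bk$grad_R)))
    g_t <- bk$grad_t
    nv <- sqrt(sum(g_v^2)); nt <- sqrt(sum(g_t^2))
    v_new <- if (nv > 0) v + step_r * g_v / nv else v
    t_new <- if (nt > 0) tr + step_t * g_t / nt else tr
    cand <- tryCatch(eval_pose(v_new, t_new),
                     slicereg_overlap_error = function(e) NULL)
    if (!is.null(cand) && cand$lncc$value > cur$lncc$value) {
      v <- v_new; tr <- t_new; cur <- cand
      if (cur$lncc$value > best$value) {
        best <- list(v = v, tr = tr, value = cur$lncc$value)
      }
    } else {
      if (is.null(cand)) lost <- TRUE
      step_t <- step_t / 2
      step_r <- step_r / 2
    }
    trace <- c(trace, best$value)
    if (step_t < cfg$tol * cfg$step_t && step_r < cfg$tol * cfg$step_r) {
      termination <- "converged"
      break
    }
  }
  if (lost && termination == "max_iterations") termination <- "lost_overlap"
  list(transform = rigid_transform(sixd_to_rot(best$v), best$tr, center = ctr,
                                   validate = FALSE),
       similarity = best$value, trace = trace, iterations = length(trace),
       termination = termination)
}

#' Classical baseline: global-NCC gradient ascent
#'
#' Intensity-based registrar in the style of the classical toolkits: global
#' NCC over the joint masks as the similarity, a fixed-step gradient scheme
#' over Euler angles (degrees) + translation (mm), gradients by central
#' finite differences. Same step-halving/best-seen policy as
#' [refine_correction()].
#'
#' @param volume an `image_volume`.
#' @param ref reference `image_slice`.
#' @param T_init starting `rigid_transform`.
#' @param cfg a [refine_config()]; `step_r` is interpreted in degrees
#'   (default 0.5 for this registrar).
#' @param h_t,h_r finite-difference half-steps (mm, degrees).
#' @return same structure as [refine_correction()], `similarity` being GNCC.
#' @export
gncc_baseline <- function(volume, ref, T_init,
                          cfg = refine_config(step_t = 0.5, step_r = 0.5),
                          h_t = 0.05, h_r = 0.05) {
  ctr <- T_init$center
  eul <- rot_to_euler(T_init$rotation)
  p <- c(T_init$translation, eul)   # tx ty tz rx ry rz
  pose_of <- function(p) rigid_transform(euler_to_rot(p[4], p[5], p[6]),
                                         p[1:3], center = ctr, validate = FALSE)
  objective <- function(p) {
    sl <- slice_like(volume, pose_of(p), ref)
    tryCatch(gncc(sl, ref), slicereg_overlap_error = function(e) NA_real_)
  }
  cur <- objective(p)
  if (is.na(cur)) overlap_error("no overlap at the initial pose")
  best <- list(p = p, value = cur)
  step <- c(rep(cfg$step_t, 3), rep(cfg$step_r, 3))
  h <- c(rep(h_t, 3), rep(h_r, 3))
  trace <- numeric(0)
  termination <- "max_iterations"
  for (it in seq_len(cfg$max_iter)) {
    g <- vapply(1:6, function(i) {
      e <- rep(0, 6); e[i] <- h[i]
      fp <- objective(p + e); fm <- objective(p - e)
      if (is.na(fp) || is.na(fm)) 0 else (fp - fm) / (2 * h[i])
    }, numeric(1))
    gt <- g[1:3]; gr <- g[4:6]
    nt <- sqrt(sum(gt^2)); nr <- sqrt(sum(gr^2))
    p_new <- p
    if (nt > 0) p_new[1:3] <- p[1:3] + step[1] * gt / nt
    if (nr > 0) p_new[4:6] <- p[4:6] + step[4] * gr / nr
    val <- objective(p_new)
    if (!is.na(val) && val > cur) {
      p <- p_new; cur <- val
      if (val > best$value) best <- list(p = p, value = val)
    } else {
      step <- step / 2
    }
    trace <- c(trace, best$value)
    if (all(step < cfg$tol * c(rep(cfg$step_t, 3), rep(cfg$step_r, 3)))) {
      termination <- "converged"
      break
    }
  }
  list(transform = pose_of(best$p), similarity = best$value, trace = trace,
       iterations = length(trace), termination = termination)
}

#' Register one 2D frame to the 3D volume
#'
#' Full per-frame pipeline: compose the tracked pose with the previous
#' correction, predict a correction with the regression network (identity
#' when no weights are supplied), and optionally refine by masked-LNCC
#' ascent. The returned corrections `delta_pred` and `delta_refined` are
#' relative to the initial transform: the registered pose of the frame is
#' `compose(initial_transform(theta_tracked, delta_prev), delta)`.
#'
#' @param volume the 3D `image_volume`.
#' @param obs a [frame_observation()].
#' @param delta_prev previous-frame correction (`rigid_transform`).
#' @param weights trained network weights (see [train_network()]), or `NULL`.
#' @param net_cfg the [network_config()] matching `weights`.
#' @param refine a [refine_config()] to enable refinement, or `NULL`.
#' @return list of class `registration_result`: `delta_pred`,
#'   `delta_refined` (or `NULL`), `theta_init`, `similarity_before`,
#'   `similarity_after`, `iterations`, `status` (`"ok"` or
#'   `"failed_overlap"`; on failure the tracked pose is passed through with
#'   identity corrections).
#' @export
register_frame <- function(volume, obs, delta_prev = identity_transform(),
                           weights = NULL, net_cfg = NULL,
                           refine = refine_config()) {
  stopifnot(inherits(obs, "frame_observation"))
  theta_init <- initial_transform(obs$theta_tracked, delta_prev)
  failed <- function() {
    structure(list(delta_pred = identity_transform(theta_init$center),
                   delta_refined = NULL, theta_init = theta_init,
                   similarity_before = NA_real_, similarity_after = NA_real_,
                   iterations = 0L, status = "failed_overlap"),
              class = "registration_result")
  }
  delta_pred <- if (!is.null(weights)) {
    vol_init <- transform_volume(volume, theta_init)
    predict_correction(vol_init, obs$ref_slice, weights, net_cfg)
  } else {
    identity_transform()
  }
  start <- compose(theta_init, delta_pred)
  sl <- slice_like(volume, start, obs$ref_slice)
  if (all(sl$mask == 0)) return(failed())
  sim_before <- tryCatch(lncc_masked(sl, obs$ref_slice, refine$sim %||% similarity_config()),
                         slicereg_overlap_error = function(e) NA_real_)
  if (is.na(sim_before)) return(failed())
  delta_refined <- NULL
  sim_after <- sim_before
  iters <- 0L
  if (!is.null(refine)) {
    rf <- tryCatch(refine_correction(volume, obs$ref_slice, start, refine),
                   slicereg_overlap_error = function(e) NULL)
    if (is.null(rf)) return(failed())
    delta_refined <- compose(invert(theta_init), rf$transform)
    sim_after <- rf$similarity
    iters <- rf$iterations
  }
  structure(list(delta_pred = delta_pred, delta_refined = delta_refined,
                 theta_init = theta_init, similarity_before = sim_before,
                 similarity_after = sim_after, iterations = iters,
                 status = "ok"),
            class = "registration_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Register a frame sequence with temporal correction chaining
#'
#' Runs [register_frame()] over a list of frames, feeding each frame's
#' correction into the next frame's initial transform (the first frame
#' starts from the identity). Set `use_prev = FALSE` to initialize every
#' frame from the tracked pose alone (for ablation of the temporal
#' stabilization).
#'
#' @param volume the 3D `image_volume`.
#' @param frames list of [frame_observation()]s.
#' @param weights,net_cfg,refine as in [register_frame()].
#' @param use_prev chain the previous correction (default TRUE).
#' @return list of `registration_result`s, one per frame.
#' @export
register_sequence <- function(volume, frames, weights = NULL, net_cfg = NULL,
                              refine = refine_config(), use_prev = TRUE) {
  delta_prev <- identity_transform()
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    res <- register_frame(volume, frames[[i]], delta_prev, weights, net_cfg, refine)
    out[[i]] <- res
    if (use_prev && res$status == "ok") {
      delta_prev <- res$delta_refined %||% res$delta_pred
    } else if (!use_prev) {
      delta_prev <- identity_transform()
    }
  }
  out
}
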