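test_that("initial transform composes tracked pose and previous correction", {
  set.seed(2)
  expect_equal(as_homogeneous(initial_transform(
    rigid_transform(translation = c(1, 2, 3)), identity_transform())),
    as_homogeneous(rigid_transform(translation = c(1, 2, 3))))
  dp <- rigid_transform(random_rotation(), rnorm(3))
  expect_equal(as_homogeneous(initial_transform(identity_transform(), dp)),
               as_homogeneous(dp))
  for (i in 1:10) {
    a <- rigid_transform(random_rotation(), rnorm(3))
    b <- rigid_transform(random_rotation(), rnorm(3))
    o <- oracle_compose(a, b)
    it <- initial_transform(a, b)
    expect_lt(max(abs(it$rotation - o$rotation)), 1e-12)
    expect_lt(max(abs(it$translation - o$translation)), 1e-12)
  }
})

test_that("LNCC refinement keeps an already-optimal pose and never degrades", {
  vol <- generate_phantom(phantom_config(shape = c(32, 32, 32), spacing = 1,
                                         seed = 31))
  pr <- make_pair(vol, slice_shape = c(28, 28), rng_seed = 3,
                  perturb = euler_perturbation())
  cfgr <- refine_config(sim = similarity_config(kernel_size = 15))
  rf <- refine_correction(vol, pr$ref_slice, pr$theta_true, cfgr)
  pe <- pose_error(rf$transform, pr$theta_true)
  expect_lt(pe$ed, 0.25)
  expect_lt(pe$ga, 0.25)
  expect_true(all(diff(rf$trace) >= -1e-12))
  expect_gte(rf$similarity, 1 - 1e-9)
})

test_that("GNCC baseline recovers a 3 mm / 2 deg perturbation on a vessel phantom", {
  vol <- generate_phantom(phantom_config(shape = c(48, 48, 48), spacing = 1,
                                         seed = 33))
  pr <- make_pair(vol, slice_shape = c(40, 40), rng_seed = 8,
                  perturb = euler_perturbation(tx = 2, ty = -2, tz = 1,
                                               rx = 1, ry = -1, rz = 2))
  rf <- gncc_baseline(vol, pr$ref_slice, pr$theta_tracked)
  pe <- pose_error(rf$transform, pr$theta_true)
  expect_lt(pe$ed, 1)
  expect_lt(pe$ga, 1)
  expect_true(all(diff(rf$trace) >= -1e-12))
})

test_that("LNCC refinement and the GNCC baseline agree on the convex blob problem", {
  vol <- blob_volume(36, sigma_mm = 6)
  ref <- extract_slice(vol, identity_transform(), c(36, 36), 1)
  start <- rigid_transform(translation = c(2, -1, 0.5))
  a <- refine_correction(vol, ref, start,
                         refine_config(sim = similarity_config(kernel_size = 21)))
  b <- gncc_baseline(vol, ref, start)
  expect_lt(sqrt(sum((a$transform$translation - b$transform$translation)^2)), 1)
  expect_lt(sqrt(sum(b$transform$translation^2)), 1)
})

test_that("register_frame handles zero motion, refinement, and field exit", {
  vol <- generate_phantom(phantom_config(shape = c(32, 32, 32), spacing = 1,
                                         seed = 35))
  pr <- make_pair(vol, slice_shape = c(28, 28), rng_seed = 4,
                  perturb = euler_perturbation())
  obs <- frame_observation(pr$ref_slice, pr$theta_tracked, 0)
  res <- register_frame(vol, obs,
                        refine = refine_config(sim = similarity_config(kernel_size = 15)))
  expect_equal(res$status, "ok")
  # perfect tracking: the refined correction stays at the identity
  pe <- pose_error(res$delta_refined, identity_transform())
  expect_lt(pe$ed, 0.25)
  expect_lt(pe$ga, 0.25)
  expect_gte(res$similarity_after, res$similarity_before - 1e-9)
  # a frame far outside the volume fails gracefully with passthrough
  far <- frame_observation(pr$ref_slice,
                           rigid_transform(translation = c(0, 0, 500)), 1)
  suppressWarnings(res2 <- register_frame(vol, far))
  expect_equal(res2$status, "failed_overlap")
  expect_equal(res2$delta_pred$translation, c(0, 0, 0))
})

test_that("known perturbations inside half the augmentation range are recovered", {
  vol <- generate_phantom(phantom_config(shape = c(48, 48, 48), spacing = 1,
                                         seed = 37))
  for (s in 1:3) {
    pr <- make_pair(vol, slice_shape = c(40, 40), rng_seed = 60 + s,
                    perturb_scale = 0.5)
    rf <- refine_correction(vol, pr$ref_slice, pr$theta_tracked,
                            refine_config(sim = similarity_config(kernel_size = 21)))
    pe <- pose_error(rf$transform, pr$theta_true)
    expect_lt(pe$ed, 1)
    expect_lt(pe$ga, 1)
  }
})

test_that("sequence registration is deterministic and chains corrections", {
  vol <- generate_phantom(phantom_config(shape = c(32, 32, 32), spacing = 1,
                                         seed = 39))
  sq <- make_sequence(vol, n_frames = 5, amplitude_mm = 2, amplitude_deg = 1,
                      slice_shape = c(28, 28), seed = 8)
  frames <- lapply(sq$frames, function(f)
    frame_observation(f$ref_slice, f$theta_tracked, f$index))
  cfgr <- refine_config(sim = similarity_config(kernel_size = 15))
  r1 <- register_sequence(vol, frames, refine = cfgr)
  r2 <- register_sequence(vol, frames, refine = cfgr)
  expect_identical(lapply(r1, function(x) x$delta_refined$translation),
                   lapply(r2, function(x) x$delta_refined$translation))
  expect_true(all(vapply(r1, function(x) x$status, "") == "ok"))
  # the refined poses track the moving ground truth
  for (i in seq_along(r1)) {
    reg <- compose(r1[[i]]$theta_init, r1[[i]]$delta_refined)
    expect_lt(pose_error(reg, sq$frames[[i]]$theta_true)$ed, 1)
  }
})

test_that("registration is equivariant under a common translation of the world", {
  vol <- generate_phantom(phantom_config(shape = c(32, 32, 32), spacing = 1,
                                         seed = 41))
  pr <- make_pair(vol, slice_shape = c(28, 28), rng_seed = 12,
                  perturb_scale = 0.3)
  cfgr <- refine_config(sim = similarity_config(kernel_size = 15))
  # integer-voxel world shift: the shifted volume is an exact array shift,
  # and the tracked pose and ground truth move by the same transform
  S <- rigid_transform(translation = c(2, -1, 1))
  vol2 <- transform_volume(vol, S)
  rf1 <- refine_correction(vol, pr$ref_slice, pr$theta_tracked, cfgr)
  rf2 <- refine_correction(vol2, pr$ref_slice,
                           compose(invert(S), pr$theta_tracked), cfgr)
  e1 <- pose_error(rf1$transform, pr$theta_true)
  e2 <- pose_error(rf2$transform, compose(invert(S), pr$theta_true))
  expect_lt(e1$ed, 1)
  expect_lt(e2$ed, 1)
  expect_lt(abs(e1$ed - e2$ed), 0.25)
})
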