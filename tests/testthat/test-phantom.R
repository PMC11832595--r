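small_cfg <- phantom_config(shape = c(32, 32, 32), spacing = 1, n_vessels = 2,
                            seed = 17)

test_that("phantom generation is seed-deterministic with valid intensities", {
  v1 <- generate_phantom(small_cfg)
  v2 <- generate_phantom(small_cfg)
  expect_identical(v1$intensities, v2$intensities)
  expect_true(all(v1$intensities >= 0 & v1$intensities <= 1))
  expect_gt(sum(v1$mask), 0)
  v3 <- generate_phantom(phantom_config(shape = c(32, 32, 32), spacing = 1,
                                        n_vessels = 2, seed = 18))
  expect_false(identical(v1$intensities, v3$intensities))
})

test_that("vessels are darker and the diaphragm brighter than parenchyma", {
  vol <- generate_phantom(small_cfg)
  ves <- attr(vol, "vessel_label") == 1
  dia <- attr(vol, "diaphragm_label") == 1
  bg <- !ves & !dia
  expect_gt(sum(ves), 0)
  contrast <- small_cfg$background - small_cfg$vessel
  expect_gt(mean(vol$intensities[bg]) - mean(vol$intensities[ves]),
            contrast / 2)
  expect_gt(mean(vol$intensities[dia]), mean(vol$intensities[bg]))
})

test_that("synthetic pairs satisfy their pose and extraction invariants", {
  vol <- generate_phantom(small_cfg)
  for (s in 1:20) {
    pr <- make_pair(vol, slice_shape = c(24, 24), rng_seed = 100 + s)
    d <- compose(pr$theta_tracked, pr$delta_gt)
    expect_lt(max(abs(as_homogeneous(d) - as_homogeneous(pr$theta_true))), 1e-9)
    # the reference slice is the exact extraction at theta_true
    re <- extract_slice(vol, pr$theta_true, c(24, 24), vol$spacing[1:2])
    expect_identical(re$intensities, pr$ref_slice$intensities)
    # overlap floor respected
    expect_gte(mean(pr$ref_slice$mask), 0.5)
    # perturbations stay inside the augmentation ranges
    p <- pr$perturb
    expect_true(abs(p$tx) <= 10 && abs(p$ty) <= 10 && abs(p$tz) <= 5)
    expect_true(abs(p$rx) <= 5 && abs(p$ry) <= 5 && abs(p$rz) <= 10)
  }
  # zero perturbation: tracked pose is the true pose, correction the identity
  pr0 <- make_pair(vol, slice_shape = c(24, 24), rng_seed = 7,
                   perturb = euler_perturbation())
  expect_equal(as_homogeneous(pr0$theta_tracked),
               as_homogeneous(pr0$theta_true), tolerance = 1e-12)
  expect_equal(as_homogeneous(pr0$delta_gt), diag(4), tolerance = 1e-12)
  # determinism
  expect_identical(make_pair(vol, c(24, 24), rng_seed = 5)$theta_true$translation,
                   make_pair(vol, c(24, 24), rng_seed = 5)$theta_true$translation)
})

test_that("synthetic sequences follow a bounded smooth trajectory", {
  vol <- generate_phantom(small_cfg)
  sq <- make_sequence(vol, n_frames = 10, amplitude_mm = 4, amplitude_deg = 2,
                      period = 10, slice_shape = c(24, 24), seed = 3)
  expect_length(sq$frames, 10)
  # frame-to-frame true-pose translation change bounded by the sinusoid slope
  step_bound <- 4 * 2 * pi / 10 * sqrt(3) + 1e-9
  for (f in 2:10) {
    dt <- sq$frames[[f]]$theta_true$translation -
      sq$frames[[f - 1]]$theta_true$translation
    expect_lte(sqrt(sum(dt^2)), step_bound)
  }
  # zero amplitude freezes the true pose
  sq0 <- make_sequence(vol, n_frames = 5, amplitude_mm = 0, amplitude_deg = 0,
                       slice_shape = c(24, 24), seed = 3)
  for (f in 2:5) {
    expect_equal(as_homogeneous(sq0$frames[[f]]$theta_true),
                 as_homogeneous(sq0$frames[[1]]$theta_true), tolerance = 1e-12)
  }
  # seeded determinism
  sq2 <- make_sequence(vol, n_frames = 10, amplitude_mm = 4, amplitude_deg = 2,
                       period = 10, slice_shape = c(24, 24), seed = 3)
  expect_identical(sq$frames[[4]]$theta_tracked$translation,
                   sq2$frames[[4]]$theta_tracked$translation)
})

test_that("preprocessing resamples, crops/pads, rescales and is idempotent", {
  set.seed(23)
  vol <- smooth_test_volume(20, spacing = 1, seed = 23)
  out <- preprocess(vol, target_shape = c(48, 40, 44))
  expect_equal(dim(out$intensities), c(48, 40, 44))
  expect_equal(out$spacing, rep(0.5, 3))
  expect_gte(min(out$intensities), 0)
  expect_lte(max(out$intensities), 1)
  expect_equal(max(out$intensities), 1)  # non-constant input spans [0, 1]
  # padded border is masked out
  expect_true(all(out$mask[1, , ] == 0))
  # idempotency: a second pass is the identity, bit for bit
  out2 <- preprocess(out, target_shape = c(48, 40, 44))
  expect_identical(out2$intensities, out$intensities)
  expect_identical(out2$mask, out$mask)
  # 2D path with its default 400 x 320 target
  sl <- image_slice(matrix(runif(40 * 30), 40, 30), spacing = 1)
  osl <- preprocess(sl)
  expect_equal(dim(osl$intensities), c(400, 320))
  expect_equal(osl$spacing, rep(0.5, 2))
  expect_error(preprocess(sl, target_spacing = -1), "positive")
})

test_that("preprocessing halves the sample spacing as expected", {
  # 1 mm input sampled at 0.5 mm: every second output voxel of the centered
  # lattice lands exactly on an input voxel center
  vol <- smooth_test_volume(21, spacing = 1, seed = 29)
  out <- preprocess(vol, target_shape = c(41, 41, 41))
  on_lattice <- out$intensities[seq(1, 41, by = 2), seq(1, 41, by = 2),
                                seq(1, 41, by = 2)]
  expect_equal(on_lattice, slicereg:::rescale01(vol$intensities),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("candidate pose sets reproduce the perturbation statistics", {
  T0 <- rigid_transform(euler_to_rot(5, -3, 10), c(4, -2, 1))
  cands <- candidate_poses(T0)
  expect_length(cands, 100)
  expect_identical(candidate_poses(T0, seed = 4)[[10]]$translation,
                   candidate_poses(T0, seed = 4)[[10]]$translation)
  big <- candidate_poses(identity_transform(), n = 10000, seed = 2)
  tx <- vapply(big, function(T) T$translation[1], numeric(1))
  expect_lt(abs(sd(tx) - 1), 0.15)
  rz <- vapply(big, function(T) rot_to_euler(T$rotation)[["rz"]], numeric(1))
  expect_lt(abs(sd(rz) - 1.5), 0.15 * 1.5)
})

test_that("LNCC candidate ranking finds the unperturbed pose", {
  vol <- generate_phantom(small_cfg)
  pr <- make_pair(vol, slice_shape = c(24, 24), rng_seed = 55,
                  perturb = euler_perturbation())
  cands <- c(list(pr$theta_true), candidate_poses(pr$theta_true, n = 30, seed = 9))
  rk <- rank_candidates(vol, pr$ref_slice, cands,
                        similarity_config(kernel_size = 11))
  expect_equal(rk$best, 1L)
  expect_equal(rk$scores[1], 1, tolerance = 1e-9)
})
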