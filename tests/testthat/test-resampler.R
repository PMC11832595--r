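test_that("reference grid uses center-relative voxel-center coordinates", {
  vol <- image_volume(array(0, c(3, 3, 3)), spacing = 1)
  g <- make_reference_grid(vol)
  expect_equal(nrow(g), 27)
  expect_equal(range(g), c(-1, 1))
  expect_true(any(apply(g, 1, function(p) all(p == c(-1, -1, -1)))))
  expect_true(any(apply(g, 1, function(p) all(p == c(1, 1, 1)))))
  # central voxel of an odd grid maps to the origin
  central <- g[ceiling(27 / 2), ]
  expect_equal(unname(central), c(0, 0, 0))
  # point count equals voxel count for random shapes
  set.seed(2)
  for (i in 1:5) {
    d <- sample(2:9, 3, replace = TRUE)
    v <- image_volume(array(0, d), spacing = runif(3, 0.3, 2))
    expect_equal(nrow(make_reference_grid(v)), prod(d))
  }
})

test_that("grid transformation is the rigid action and respects composition", {
  vol <- image_volume(array(0, c(4, 5, 6)), spacing = c(0.5, 1, 2))
  g <- make_reference_grid(vol)
  expect_equal(transform_grid(g, identity_transform()), g)
  tt <- rigid_transform(translation = c(3, -1, 2))
  expect_equal(unclass(transform_grid(g, tt)),
               unclass(sweep(g, 2, c(3, -1, 2), "+")), ignore_attr = TRUE)
  set.seed(4)
  for (i in 1:10) {
    A <- rigid_transform(random_rotation(), rnorm(3))
    B <- rigid_transform(random_rotation(), rnorm(3))
    lhs <- transform_grid(transform_grid(g, A), B)
    rhs <- transform_grid(g, compose(B, A))
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("trilinear interpolation matches the 8-neighbor oracle", {
  set.seed(10)
  vol <- image_volume(array(runif(10 * 8 * 6), c(10, 8, 6)),
                      spacing = c(0.7, 1.3, 2.1))
  # exact at voxel centers
  g <- make_reference_grid(vol)
  res <- interpolate(vol, g)
  expect_identical(res$value, as.numeric(vol$intensities))
  # midpoint between two voxel centers along one axis is the mean
  p_mid <- (g[1, ] + g[2, ]) / 2
  expect_equal(interpolate(vol, rbind(p_mid))$value,
               mean(vol$intensities[1:2, 1, 1]), tolerance = 1e-12)
  # random interior points vs brute-force oracle
  ext <- (dim(vol$intensities) - 1) / 2 * vol$spacing
  pts <- cbind(runif(1000, -ext[1], ext[1]), runif(1000, -ext[2], ext[2]),
               runif(1000, -ext[3], ext[3]))
  res <- interpolate(vol, pts)
  ora <- apply(pts, 1, oracle_trilinear, vol = vol)
  expect_lt(max(abs(res$value - ora)), 1e-6)
  # out-of-bounds: zero fill, zero validity, never non-finite
  far <- cbind(runif(100, ext[1] + 1, ext[1] + 50), 0, 0)
  res <- interpolate(vol, far)
  expect_true(all(res$value == 0) && all(res$valid == 0))
  expect_true(all(is.finite(res$value)))
})

test_that("interpolation reproduces a linear ramp exactly in the interior", {
  a <- c(0.03, -0.02, 0.05); n <- 16
  ax <- ((seq_len(n) - 1) - (n - 1) / 2)
  ramp <- 0.5 + a[1] * ax[rep(1:n, n * n)] +
    a[2] * ax[rep(rep(1:n, each = n), n)] + a[3] * ax[rep(1:n, each = n * n)]
  vol <- image_volume(array(ramp, c(n, n, n)), spacing = 1)
  set.seed(3)
  pts <- matrix(runif(3000, -6, 6), ncol = 3)
  res <- interpolate(vol, pts)
  expect_lt(max(abs(res$value - (0.5 + pts %*% a))), 1e-12)
})

test_that("volume resampling: identity copy, integer shift, bounded round trip", {
  set.seed(6)
  vol <- smooth_test_volume(24, sigma = 3.5)  # band-limited: two passes stay bounded
  expect_identical(transform_volume(vol, identity_transform())$intensities,
                   vol$intensities)
  # integer-voxel axis-aligned translation shifts the array with a zero band
  sh <- transform_volume(vol, rigid_transform(translation = c(3, 0, 0)))
  expect_equal(sh$intensities[1:21, , ], vol$intensities[4:24, , ])
  expect_true(all(sh$intensities[22:24, , ] == 0))
  # two interpolation passes stay within 0.02 intensity units in the interior
  T <- rigid_transform(euler_to_rot(3, -2, 4), c(1.3, -0.7, 0.9))
  back <- transform_volume(transform_volume(vol, T), invert(T))
  core <- 7:18
  expect_lt(max(abs(back$intensities[core, core, core] -
                      vol$intensities[core, core, core])), 0.02)
})

test_that("slice extraction at identity is bit-equal to plane indexing", {
  set.seed(9)
  vol <- image_volume(array(runif(15^3), c(15, 15, 15)), spacing = c(0.8, 0.8, 1.1))
  sl <- extract_slice(vol, identity_transform(), c(15, 15), c(0.8, 0.8))
  expect_identical(sl$intensities, vol$intensities[, , 8])
  # in-plane integer-pixel translation shifts the central plane
  sl2 <- extract_slice(vol, rigid_transform(translation = c(2 * 0.8, 0, 0)),
                       c(15, 15), c(0.8, 0.8))
  expect_equal(sl2$intensities[1:13, ], vol$intensities[3:15, , 8])
})

test_that("oblique slices of a linear ramp match the closed form", {
  a <- c(0.01, 0.04, -0.03); n <- 20
  ax <- (seq_len(n) - 1) - (n - 1) / 2
  ramp <- 0.5 + outer(outer(a[1] * ax, a[2] * ax, "+"), a[3] * ax, "+")
  vol <- image_volume(array(ramp, c(n, n, n)), spacing = 1)
  T <- rigid_transform(euler_to_rot(8, -5, 12), c(0.4, -1.1, 0.8))
  sl <- extract_slice(vol, T, c(10, 10), 0.9)
  pts <- apply_transform(T, slicereg:::slice_plane_points(c(10, 10), 0.9))
  expected <- 0.5 + pts %*% a
  expect_lt(max(abs(as.numeric(sl$intensities) - expected)), 1e-6)
})

test_that("analytic pose gradients match finite differences", {
  vol <- smooth_test_volume(28, seed = 12, sigma = 3.5)
  T0 <- rigid_transform(euler_to_rot(4, -6, 10), c(1.2, -0.8, 2.1))
  shape <- c(20, 20); spc <- 1
  w <- matrix(1 / prod(shape), shape[1], shape[2])  # mean-intensity objective
  bk <- slice_pose_backward(vol, T0, w, spc)
  v6 <- slicereg:::as_sixd_vec(rot_to_6d(T0$rotation))
  g9 <- c(as.numeric(crossprod(sixd_jacobian(v6), as.numeric(bk$grad_R))), bk$grad_t)
  obj <- function(v6, tr) {
    mean(extract_slice(vol, rigid_transform(sixd_to_rot(v6), tr, validate = FALSE),
                       shape, spc)$intensities)
  }
  h <- 1e-5
  fd <- sapply(1:9, function(i) {
    dv <- rep(0, 9); dv[i] <- h
    (obj(v6 + dv[1:6], T0$translation + dv[7:9]) -
       obj(v6 - dv[1:6], T0$translation - dv[7:9])) / (2 * h)
  })
  expect_lt(sqrt(sum((g9 - fd)^2)) / sqrt(sum(fd^2)), 1e-3)
})

test_that("a plane that misses the volume is flagged empty", {
  vol <- image_volume(array(0.5, c(8, 8, 8)), spacing = 1)
  T <- rigid_transform(translation = c(0, 0, 100))
  expect_warning(sl <- extract_slice(vol, T, c(8, 8), 1), "outside")
  expect_true(isTRUE(attr(sl, "empty")))
  expect_true(all(sl$mask == 0) && all(sl$intensities == 0))
})
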