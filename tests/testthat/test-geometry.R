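test_that("6D representation round-trips SO(3) and Gram-Schmidt always yields rotations", {
  set.seed(42)
  for (i in 1:300) {
    R <- random_rotation()
    expect_lt(max(abs(sixd_to_rot(rot_to_6d(R)) - R)), 1e-9)
  }
  # strongly non-orthonormal inputs still map into SO(3)
  for (i in 1:300) {
    v <- rnorm(6, sd = 3)
    R <- sixd_to_rot(v)
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_lt(abs(det(R) - 1), 1e-9)
  }
  expect_equal(rot_to_6d(diag(3))$a1, c(1, 0, 0))
  expect_equal(rot_to_6d(diag(3))$a2, c(0, 1, 0))
  Rz90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  expect_equal(rot_to_6d(Rz90)$a1, c(0, 1, 0))
  expect_equal(rot_to_6d(Rz90)$a2, c(-1, 0, 0))
  expect_equal(sixd_to_rot(c(1, 0, 0, 0, 1, 0)), diag(3))
  # Gram-Schmidt arithmetic on a non-orthonormal pair
  expect_equal(sixd_to_rot(c(2, 0, 0, 1, 1, 0)), diag(3))
})

test_that("degenerate and invalid rotation inputs are rejected", {
  expect_error(rot_to_6d(matrix(1, 3, 3)), "orthonormal")
  expect_error(rot_to_6d(diag(c(1, 1, -1))), "determinant")
  expect_error(sixd_to_rot(c(0, 0, 0, 0, 1, 0)), "zero norm|degenerate")
  expect_error(sixd_to_rot(c(1, 0, 0, 2, 0, 0)), "collinear")
})

test_that("Gram-Schmidt Jacobian matches central finite differences", {
  set.seed(7)
  for (rep in 1:5) {
    v <- rnorm(6)
    J <- sixd_jacobian(v)
    h <- 1e-6
    Jfd <- sapply(1:6, function(i) {
      e <- rep(0, 6); e[i] <- h
      (as.numeric(sixd_to_rot(v + e)) - as.numeric(sixd_to_rot(v - e))) / (2 * h)
    })
    expect_lt(max(abs(J - Jfd)), 1e-6)
  }
})

test_that("composition matches the homogeneous-matrix oracle and group axioms", {
  set.seed(3)
  for (i in 1:50) {
    A <- rigid_transform(random_rotation(), rnorm(3, sd = 5))
    B <- rigid_transform(random_rotation(), rnorm(3, sd = 5))
    C <- rigid_transform(random_rotation(), rnorm(3, sd = 5))
    AB <- compose(A, B)
    o <- oracle_compose(A, B)
    expect_lt(max(abs(AB$rotation - o$rotation)), 1e-12)
    expect_lt(max(abs(AB$translation - o$translation)), 1e-12)
    # identity is a two-sided unit
    expect_lt(max(abs(as_homogeneous(compose(A, identity_transform())) -
                        as_homogeneous(A))), 1e-12)
    expect_lt(max(abs(as_homogeneous(compose(identity_transform(), A)) -
                        as_homogeneous(A))), 1e-12)
    # inverse and associativity
    expect_lt(max(abs(as_homogeneous(compose(A, invert(A))) - diag(4))), 1e-9)
    expect_lt(max(abs(as_homogeneous(compose(compose(A, B), C)) -
                        as_homogeneous(compose(A, compose(B, C))))), 1e-9)
  }
  # pure translations add
  t1 <- rigid_transform(translation = c(1, 2, 3))
  t2 <- rigid_transform(translation = c(4, 5, 6))
  expect_equal(compose(t1, t2)$translation, c(5, 7, 9))
  expect_equal(compose(t1, t2)$rotation, diag(3))
  # mismatched centers are rejected
  expect_error(compose(t1, rigid_transform(center = c(1, 0, 0))), "center")
})

test_that("geodesic error matches the quaternion axis-angle oracle", {
  R <- random_rotation(1)
  expect_equal(geodesic_error(R, R), 0)
  Rz90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  expect_equal(geodesic_error(diag(3), Rz90), 90, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:200) {
    Ra <- random_rotation(); Rb <- random_rotation()
    expect_lt(abs(geodesic_error(Ra, Rb) - oracle_rot_angle(Ra %*% t(Rb))), 1e-9)
    # symmetry and bounds
    expect_lt(abs(geodesic_error(Ra, Rb) - geodesic_error(Rb, Ra)), 1e-9)
    expect_gte(geodesic_error(Ra, Rb), 0)
    expect_lte(geodesic_error(Ra, Rb), 180)
  }
  # triangle inequality on sampled triples
  for (i in 1:50) {
    Ra <- random_rotation(); Rb <- random_rotation(); Rc <- random_rotation()
    expect_lte(geodesic_error(Ra, Rc),
               geodesic_error(Ra, Rb) + geodesic_error(Rb, Rc) + 1e-9)
  }
})

test_that("Euler conversion round-trips inside the gimbal-safe range", {
  set.seed(5)
  for (i in 1:100) {
    ang <- c(runif(1, -80, 80), runif(1, -80, 80), runif(1, -170, 170))
    R <- euler_to_rot(ang[1], ang[2], ang[3])
    back <- rot_to_euler(R)
    expect_equal(unname(back), ang, tolerance = 1e-9)
  }
})

test_that("perturbation sampler is seeded and respects the augmentation ranges", {
  p1 <- sample_perturbation(99)
  p2 <- sample_perturbation(99)
  expect_identical(p1, p2)
  set.seed(123)
  draws <- t(replicate(1000, unlist(sample_perturbation()[1:6])))
  expect_true(all(abs(draws[, "tx"]) <= 10) && all(abs(draws[, "ty"]) <= 10))
  expect_true(all(abs(draws[, "tz"]) <= 5))
  expect_true(all(abs(draws[, "rx"]) <= 5) && all(abs(draws[, "ry"]) <= 5))
  expect_true(all(abs(draws[, "rz"]) <= 10))
  # scaled draws shrink proportionally
  half <- t(replicate(200, unlist(sample_perturbation(scale = 0.5)[1:6])))
  expect_true(all(abs(half[, "tx"]) <= 5) && all(abs(half[, "tz"]) <= 2.5))
  # uniform moments: means within 3 standard errors of 0
  big <- t(replicate(10000, unlist(sample_perturbation()[1:6])))
  se <- c(10, 10, 5, 5, 5, 10) / sqrt(3) / sqrt(nrow(big))
  expect_true(all(abs(colMeans(big)) < 3 * se))
})

test_that("loss weights normalize to a unit sum", {
  w <- loss_weights(20, 1, 10)
  expect_equal(w$alpha + w$beta + w$gamma, 1, tolerance = 1e-12)
  expect_equal(c(w$alpha, w$beta, w$gamma), c(20, 1, 10) / 31, tolerance = 1e-12)
  expect_error(loss_weights(-1, 1, 1), "nonnegative")
})

test_that("transform JSON serialization round-trips bit-exactly", {
  set.seed(8)
  T <- rigid_transform(random_rotation(), rnorm(3), center = c(1.5, -2.25, 3))
  f <- tempfile(fileext = ".json")
  write_transform(T, f)
  T2 <- read_transform(f)
  expect_identical(T$rotation, T2$rotation)
  expect_identical(T$translation, T2$translation)
  expect_identical(T$center, T2$center)
  unlink(f)
})
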