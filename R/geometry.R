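# SE(3)/SO(3) arithmetic: rigid transforms about the volume center, the
# continuous 6D rotation representation, geodesic errors and pose perturbations.
#
# Conventions used throughout the package:
#  * points are physical coordinates in mm, relative to the 3D volume center
#    (the transform's `center` field records where that center sits in world
#    space, and composition requires matching centers);
#  * a transform acts as y = R x + t on center-relative coordinates;
#  * Euler angles are intrinsic rotations applied in x -> y -> z order,
#    right-handed, i.e. R = Rx(rx) Ry(ry) Rz(rz);
#  * angles are radians internally, degrees at API/report boundaries.

ROT_TOL <- 1e-6

#' Rigid transform in 3D
#'
#' Constructs an SE(3) rigid transform acting on center-relative physical
#' coordinates (mm) as `y = R x + t`. The rotation center (mm, world
#' coordinates) is carried as metadata so that composition of transforms
#' defined about different centers can be rejected.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1).
#' @param translation numeric length-3 translation in mm.
#' @param center numeric length-3 rotation center in mm (default origin).
#' @param validate check the rotation for orthonormality (default TRUE).
#' @return an object of class `rigid_transform` with fields `rotation`,
#'   `translation`, `center`.
#' @examples
#' t1 <- rigid_transform(translation = c(1, 2, 3))
#' compose(t1, invert(t1))
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0), validate = TRUE) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  center <- as.numeric(center)
  stopifnot(length(translation) == 3, length(center) == 3)
  if (validate) assert_rotation(rotation)
  structure(list(rotation = rotation, translation = translation,
                 center = center),
            class = "rigid_transform")
}

assert_rotation <- function(R, tol = ROT_TOL) {
  if (!all(is.finite(R))) stop("rotation contains non-finite entries")
  err <- max(abs(crossprod(R) - diag(3)))
  if (err > tol) {
    stop(sprintf("matrix is not orthonormal (max |R'R - I| = %.3g)", err))
  }
  if (abs(det(R) - 1) > tol) {
    stop(sprintf("matrix has determinant %.6f, not +1 (improper rotation?)", det(R)))
  }
  invisible(TRUE)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n")
  cat("  rotation (geodesic angle ", format(geodesic_error(x$rotation, diag(3)), digits = 4),
      " deg from identity)\n", sep = "")
  cat("  translation (mm):", format(x$translation, digits = 6), "\n")
  cat("  center (mm):     ", format(x$center, digits = 6), "\n")
  invisible(x)
}

#' Identity transform
#' @param center rotation center (mm).
#' @return the identity `rigid_transform`.
#' @export
identity_transform <- function(center = c(0, 0, 0)) {
  rigid_transform(center = center, validate = FALSE)
}

#' Compose two rigid transforms
#'
#' Returns the transform mapping `x` to `A(B(x))`, i.e. the homogeneous
#' matrix product `A %*% B`. Both transforms must share the same rotation
#' center convention.
#'
#' @param A,B `rigid_transform` objects.
#' @return a `rigid_transform`.
#' @export
compose <- function(A, B) {
  stopifnot(inherits(A, "rigid_transform"), inherits(B, "rigid_transform"))
  if (max(abs(A$center - B$center)) > 1e-9) {
    stop("cannot compose transforms with different rotation centers")
  }
  rigid_transform(rotation = A$rotation %*% B$rotation,
                  translation = as.numeric(A$rotation %*% B$translation) + A$translation,
                  center = A$center, validate = FALSE)
}

#' Invert a rigid transform
#' @param T a `rigid_transform`.
#' @return the inverse `rigid_transform`.
#' @export
invert <- function(T) {
  stopifnot(inherits(T, "rigid_transform"))
  Rt <- t(T$rotation)
  rigid_transform(rotation = Rt, translation = as.numeric(-Rt %*% T$translation),
                  center = T$center, validate = FALSE)
}

#' Homogeneous 4x4 matrix of a rigid transform
#' @param T a `rigid_transform`.
#' @return 4x4 numeric matrix.
#' @export
as_homogeneous <- function(T) {
  M <- diag(4)
  M[1:3, 1:3] <- T$rotation
  M[1:3, 4] <- T$translation
  M
}

#' Apply a rigid transform to points
#' @param T a `rigid_transform`.
#' @param pts n x 3 matrix of center-relative coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
apply_transform <- function(T, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(pts %*% t(T$rotation), 2, T$translation, "+")
}

# ---- 6D rotation representation --------------------------------------------

#' Rotation matrix to continuous 6D representation
#'
#' Drops the last column of the rotation matrix, keeping the first two
#' columns `a1`, `a2`. This is the continuous 6D parameterization of SO(3)
#' that avoids the discontinuities of Euler angles and quaternions.
#'
#' @param R 3x3 rotation matrix.
#' @return list with fields `a1`, `a2` (numeric length 3), class `rotation6d`.
#' @export
rot_to_6d <- function(R) {
  R <- matrix(as.numeric(R), 3, 3)
  assert_rotation(R)
  structure(list(a1 = R[, 1], a2 = R[, 2]), class = "rotation6d")
}

#' 6D representation to rotation matrix (Gram-Schmidt)
#'
#' Maps two (not necessarily orthonormal) 3-vectors to a rotation matrix:
#' `b1 = N(a1)`, `b2 = N(a2 - (b1.a2) b1)`, `b3 = b1 x b2`, assembled as
#' columns. The output is exactly orthonormal with determinant +1 for any
#' non-degenerate input, which is what makes the 6D representation safe as a
#' regression target.
#'
#' @param v a `rotation6d`, or a numeric vector of length 6
#'   (`c(a1, a2)`).
#' @return 3x3 rotation matrix.
#' @export
sixd_to_rot <- function(v) {
  v <- as_sixd_vec(v)
  a1 <- v[1:3]; a2 <- v[4:6]
  if (!all(is.finite(v))) stop("6D input contains non-finite values")
  n1 <- sqrt(sum(a1^2))
  if (n1 < 1e-12) stop("degenerate 6D input: a1 has (near-)zero norm")
  b1 <- a1 / n1
  u2 <- a2 - sum(b1 * a2) * b1
  n2 <- sqrt(sum(u2^2))
  if (n2 < 1e-12) stop("degenerate 6D input: a1 and a2 are (near-)collinear")
  b2 <- u2 / n2
  b3 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  cbind(b1, b2, b3, deparse.level = 0)
}

as_sixd_vec <- function(v) {
  if (inherits(v, "rotation6d")) c(v$a1, v$a2) else {
    stopifnot(length(v) == 6)
    as.numeric(v)
  }
}

#' Jacobian of the Gram-Schmidt map
#'
#' Analytic 9x6 Jacobian of `vec(sixd_to_rot(v))` (column-major vec) with
#' respect to the 6 input components. Used to backpropagate losses through
#' the rotation head and through pose refinement.
#'
#' @param v 6D input as in [sixd_to_rot()].
#' @return 9x6 numeric matrix.
#' @export
sixd_jacobian <- function(v) {
  v <- as_sixd_vec(v)
  a1 <- v[1:3]; a2 <- v[4:6]
  n1 <- sqrt(sum(a1^2))
  b1 <- a1 / n1
  P1 <- (diag(3) - tcrossprod(b1)) / n1          # db1/da1
  d <- sum(b1 * a2)
  u2 <- a2 - d * b1
  n2 <- sqrt(sum(u2^2))
  b2 <- u2 / n2
  P2 <- (diag(3) - tcrossprod(b2)) / n2          # db2/du2
  du_db1 <- -(tcrossprod(b1, a2) + d * diag(3))  # du2/db1
  du_da2 <- diag(3) - tcrossprod(b1)             # du2/da2
  db1_da1 <- P1
  db2_da1 <- P2 %*% du_db1 %*% P1
  db2_da2 <- P2 %*% du_da2
  cx <- function(w) matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  db3_db1 <- -cx(b2)                             # d(b1 x b2)/db1
  db3_db2 <- cx(b1)
  db3_da1 <- db3_db1 %*% db1_da1 + db3_db2 %*% db2_da1
  db3_da2 <- db3_db2 %*% db2_da2
  J <- matrix(0, 9, 6)
  J[1:3, 1:3] <- db1_da1
  J[4:6, 1:3] <- db2_da1
  J[4:6, 4:6] <- db2_da2
  J[7:9, 1:3] <- db3_da1
  J[7:9, 4:6] <- db3_da2
  J
}

# ---- rotation metrics ------------------------------------------------------

#' Geodesic angular error between two rotations
#'
#' The rotation angle of `Ra %*% t(Rb)`, i.e. the minimal angle taking one
#' rotation to the other: `acos((trace(Ra Rb^-1) - 1)/2)`. The arccos
#' argument is clamped to `[-1, 1]` to absorb floating-point drift of the
#' trace.
#'
#' @param Ra,Rb 3x3 rotation matrices or `rigid_transform` objects.
#' @param degrees return degrees (default) or radians.
#' @return angle in `[0, 180]` degrees (or `[0, pi]` radians).
#' @export
geodesic_error <- function(Ra, Rb, degrees = TRUE) {
  if (inherits(Ra, "rigid_transform")) Ra <- Ra$rotation
  if (inherits(Rb, "rigid_transform")) Rb <- Rb$rotation
  c_ <- (sum(diag(Ra %*% t(Rb))) - 1) / 2
  ang <- acos(pmin(1, pmax(-1, c_)))
  if (degrees) ang * 180 / pi else ang
}

# Gradient of the geodesic angle (radians) with respect to Ra, given Rb.
# d/dRa acos((tr(Ra Rb^T)-1)/2) = -Rb / (2 sqrt(1 - c^2)); the denominator is
# floored to keep training gradients finite at (near-)perfect alignment.
geodesic_grad <- function(Ra, Rb, eps = 1e-6) {
  c_ <- (sum(diag(Ra %*% t(Rb))) - 1) / 2
  c_ <- pmin(1, pmax(-1, c_))
  -Rb / (2 * sqrt(max(1 - c_^2, eps)))
}

# ---- Euler angles ----------------------------------------------------------

#' Euler angles to rotation matrix
#'
#' Intrinsic rotations applied in x -> y -> z order (the package's fixed
#' convention): `R = Rx(rx) Ry(ry) Rz(rz)`.
#'
#' @param rx,ry,rz angles.
#' @param degrees interpret the angles as degrees (default TRUE).
#' @return 3x3 rotation matrix.
#' @export
euler_to_rot <- function(rx, ry, rz, degrees = TRUE) {
  if (degrees) {
    rx <- rx * pi / 180; ry <- ry * pi / 180; rz <- rz * pi / 180
  }
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3, 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

#' Rotation matrix to Euler angles (x -> y -> z intrinsic)
#'
#' Inverse of [euler_to_rot()] away from the gimbal lock at `|ry| = 90` deg.
#'
#' @param R 3x3 rotation matrix.
#' @param degrees return degrees (default TRUE).
#' @return named numeric vector `c(rx, ry, rz)`.
#' @export
rot_to_euler <- function(R, degrees = TRUE) {
  # R = Rx Ry Rz  =>  R[1,3] = sin(ry); R[1,2] = -cos(ry) sin(rz);
  # R[1,1] = cos(ry) cos(rz); R[2,3] = -sin(rx) cos(ry); R[3,3] = cos(rx) cos(ry)
  sy <- pmin(1, pmax(-1, R[1, 3]))
  ry <- asin(sy)
  if (abs(cos(ry)) > 1e-9) {
    rx <- atan2(-R[2, 3], R[3, 3])
    rz <- atan2(-R[1, 2], R[1, 1])
  } else {
    # gimbal lock: rz is unrecoverable, fold it into rx
    rx <- atan2(R[3, 2], R[2, 2])
    rz <- 0
  }
  ang <- c(rx = rx, ry = ry, rz = rz)
  if (degrees) ang * 180 / pi else ang
}

# ---- perturbations ---------------------------------------------------------

#' Euler-angle pose perturbation
#'
#' Holds a small rigid perturbation as per-axis translations (mm) and Euler
#' angles (degrees), with the package's fixed intrinsic x->y->z convention.
#'
#' @param tx,ty,tz translations in mm.
#' @param rx,ry,rz rotations in degrees.
#' @return an object of class `euler_perturbation`.
#' @export
euler_perturbation <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  structure(list(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz,
                 convention = "intrinsic-xyz"),
            class = "euler_perturbation")
}

#' Convert an Euler perturbation to a rigid transform
#' @param p an `euler_perturbation`.
#' @param center rotation center (mm).
#' @return a `rigid_transform`.
#' @export
perturbation_to_transform <- function(p, center = c(0, 0, 0)) {
  stopifnot(inherits(p, "euler_perturbation"))
  rigid_transform(rotation = euler_to_rot(p$rx, p$ry, p$rz),
                  translation = c(p$tx, p$ty, p$tz),
                  center = center, validate = FALSE)
}

#' Sample a pose perturbation from the augmentation distribution
#'
#' Draws a uniform pose perturbation matching the training-augmentation
#' statistics of freehand-probe tracking error: translations
#' tx, ty ~ U(-10, 10) mm, tz ~ U(-5, 5) mm; rotations rx, ry ~ U(-5, 5) deg,
#' rz ~ U(-10, 10) deg. A `scale` factor shrinks all ranges proportionally
#' (e.g. `scale = 0.5` for half-range draws).
#'
#' @param rng_seed integer seed; the draw is deterministic given the seed.
#'   `NULL` uses (and advances) the current RNG state.
#' @param scale multiplier applied to every range (default 1).
#' @return an `euler_perturbation`.
#' @export
sample_perturbation <- function(rng_seed = NULL, scale = 1) {
  draw <- function() {
    euler_perturbation(tx = runif(1, -10, 10) * scale,
                       ty = runif(1, -10, 10) * scale,
                       tz = runif(1, -5, 5) * scale,
                       rx = runif(1, -5, 5) * scale,
                       ry = runif(1, -5, 5) * scale,
                       rz = runif(1, -10, 10) * scale)
  }
  if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw())
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Uniformly distributed random rotation
#'
#' Draws a rotation uniformly from SO(3) (via QR decomposition of a Gaussian
#' matrix with sign correction). Useful for property tests and fixtures.
#'
#' @param rng_seed optional integer seed.
#' @return 3x3 rotation matrix.
#' @export
random_rotation <- function(rng_seed = NULL) {
  draw <- function() {
    M <- matrix(rnorm(9), 3, 3)
    qr_ <- qr(M)
    Q <- qr.Q(qr_)
    Q <- Q %*% diag(sign(diag(qr.R(qr_))))
    if (det(Q) < 0) Q[, 3] <- -Q[, 3]
    Q
  }
  if (is.null(rng_seed)) draw() else with_seed(rng_seed, draw())
}

# ---- loss weights ----------------------------------------------------------

#' Loss weights for the combined registration loss
#'
#' Normalizes three nonnegative weights to sum to 1. The default ratio
#' 20:1:10 balances the image term (1 - LNCC), the translation MSE (mm^2)
#' and the geodesic rotation term (radians).
#'
#' @param alpha,beta,gamma nonnegative weights (ratio; normalized internally).
#' @return list with `alpha`, `beta`, `gamma` summing to 1, class `loss_weights`.
#' @export
loss_weights <- function(alpha = 20, beta = 1, gamma = 10) {
  w <- c(alpha, beta, gamma)
  if (any(!is.finite(w)) || any(w < 0) || sum(w) <= 0) {
    stop("weights must be nonnegative with a positive sum")
  }
  w <- w / sum(w)
  structure(list(alpha = w[1], beta = w[2], gamma = w[3]), class = "loss_weights")
}

# ---- serialization ---------------------------------------------------------

#' Write a rigid transform to JSON
#'
#' Serializes rotation (9 numbers, row-major), translation and center in mm,
#' and the coordinate convention string, at 17 significant digits so the
#' decimal representation round-trips bit-exactly.
#'
#' @param T a `rigid_transform`.
#' @param path output file path.
#' @export
write_transform <- function(T, path) {
  stopifnot(inherits(T, "rigid_transform"))
  obj <- list(rotation = as.numeric(t(T$rotation)),
              translation_mm = T$translation,
              center_mm = T$center,
              convention = "center-relative; y = R x + t; row-major rotation")
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = I(17))
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path file written by [write_transform()].
#' @return a `rigid_transform`.
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(rotation = matrix(obj$rotation, 3, 3, byrow = TRUE),
                  translation = obj$translation_mm,
                  center = obj$center_mm)
}
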