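# Independent oracles used by the test suite. These deliberately avoid the
# package's computational paths: plain loops, quaternion conversions and
# homogeneous matrix products.

# Rotation angle (degrees) via quaternion extraction (Shepperd's method) --
# an axis-angle route independent of the trace/arccos formula.
oracle_rot_angle <- function(R) {
  tr <- sum(diag(R))
  qs <- c(1 + tr, 1 + 2 * R[1, 1] - tr, 1 + 2 * R[2, 2] - tr, 1 + 2 * R[3, 3] - tr)
  i <- which.max(qs)
  q <- numeric(4)
  s <- 2 * sqrt(max(qs[i], 0))
  if (i == 1) {
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (i == 2) {
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (i == 3) {
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1])) * 180 / pi
}

# Homogeneous 4x4 product oracle for transform composition.
oracle_compose <- function(A, B) {
  MA <- rbind(cbind(A$rotation, A$translation), c(0, 0, 0, 1))
  MB <- rbind(cbind(B$rotation, B$translation), c(0, 0, 0, 1))
  M <- MA %*% MB
  list(rotation = M[1:3, 1:3], translation = M[1:3, 4])
}

# Brute-force trilinear interpolation: explicit 8-neighbor weighted sum at a
# single center-relative physical point; NA outside the volume.
oracle_trilinear <- function(vol, p) {
  d <- dim(vol$intensities)
  v <- p / vol$spacing + (d - 1) / 2
  if (any(v < 0) || any(v > d - 1)) return(NA_real_)
  i0 <- pmin(floor(v), d - 2)
  i0 <- pmax(i0, 0)
  f <- v - i0
  s <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
    idx <- i0 + c(dx, dy, dz) + 1
    s <- s + w * vol$intensities[idx[1], idx[2], idx[3]]
  }
  s
}

# Brute-force masked windowed NCC: double loop over window centers, explicit
# masked means/variances, half-(in-image-)area occupancy rule, variance
# floors max(va, eps).
oracle_lncc <- function(a, b, ma, mb, k, eps = 1e-5) {
  nr <- nrow(a); nc <- ncol(a); r <- k %/% 2
  m <- (ma != 0) & (mb != 0)
  vals <- c()
  for (j in 1:nc) for (i in 1:nr) {
    i0 <- max(1, i - r); i1 <- min(nr, i + r)
    j0 <- max(1, j - r); j1 <- min(nc, j + r)
    area <- (i1 - i0 + 1) * (j1 - j0 + 1)
    mw <- m[i0:i1, j0:j1]
    n <- sum(mw)
    if (n == 0 || n < area / 2) next
    aw <- a[i0:i1, j0:j1][mw]
    bw <- b[i0:i1, j0:j1][mw]
    cov <- sum((aw - mean(aw)) * (bw - mean(bw)))
    va <- sum((aw - mean(aw))^2)
    vb <- sum((bw - mean(bw))^2)
    vals <- c(vals, cov / sqrt(max(va, eps) * max(vb, eps)))
  }
  mean(vals)
}

# Irregular polygonal mask with a guaranteed coverage floor (redraws until
# the mask fills at least `min_frac` of the image, so windowed metrics have
# usable windows).
random_polygon_mask <- function(nr, nc, n_vertices = 5, min_frac = 0.3) {
  repeat {
    mk <- random_polygon_mask_once(nr, nc, n_vertices)
    if (mean(mk) >= min_frac) return(mk)
  }
}

random_polygon_mask_once <- function(nr, nc, n_vertices = 5) {
  ang <- sort(runif(n_vertices, 0, 2 * pi))
  rad <- runif(n_vertices, 0.3, 0.55)
  cx <- nr / 2 + runif(1, -2, 2); cy <- nc / 2 + runif(1, -2, 2)
  vx <- cx + rad * nr * cos(ang); vy <- cy + rad * nc * sin(ang)
  inside <- function(x, y) {
    s <- 0
    nv <- length(vx)
    for (v in seq_len(nv)) {
      w <- v %% nv + 1
      if ((vy[v] > y) != (vy[w] > y)) {
        xi <- vx[v] + (y - vy[v]) / (vy[w] - vy[v]) * (vx[w] - vx[v])
        if (x < xi) s <- s + 1
      }
    }
    s %% 2 == 1
  }
  mk <- matrix(0, nr, nc)
  for (j in 1:nc) for (i in 1:nr) if (inside(i, j)) mk[i, j] <- 1
  mk
}

# Smooth band-limited phantom for differentiability and round-trip tests.
smooth_test_volume <- function(n = 32, spacing = 1, seed = 1, sigma = 2.5) {
  slicereg:::with_seed(seed, {
    arr <- array(runif(n^3), c(n, n, n))
    arr <- slicereg:::`.gauss_smooth3_cpp`(arr, rep(sigma, 3))
    arr <- (arr - min(arr)) / (max(arr) - min(arr))
    image_volume(arr, spacing = spacing)
  })
}

# Isotropic Gaussian blob volume (closed-form, convex similarity landscape).
blob_volume <- function(n = 48, spacing = 1, sigma_mm = 6) {
  ax <- ((seq_len(n) - 1) - (n - 1) / 2) * spacing
  g1 <- exp(-ax^2 / (2 * sigma_mm^2))
  arr <- outer(outer(g1, g1), g1)
  image_volume(arr, spacing = spacing)
}
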