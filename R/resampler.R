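# The volume slicing module ("volume spatial transformer"): sampling-grid
# generation, trilinear interpolation, volume resampling and 2D slice
# extraction, all with analytic gradients with respect to pose parameters.
#
# Voxel (i, j, k) (1-based) sits at physical coordinate
#   origin + (index - 1) * spacing  (mm, world frame);
# all sampling math is done in coordinates relative to the volume center,
#   x = (index - 1 - (dim - 1)/2) * spacing,
# matching the transform convention in geometry.R.

#' 3D image volume
#'
#' An intensity grid with voxel spacing, origin and a binary validity mask.
#'
#' @param intensities 3D numeric array with values (nominally) in `[0, 1]`.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param origin physical coordinate of voxel (1,1,1) in mm (length 3).
#' @param mask binary 3D array of the same shape; default all-valid.
#' @return object of class `image_volume`.
#' @export
image_volume <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         mask = NULL) {
  stopifnot(length(dim(intensities)) == 3, all(is.finite(intensities)))
  spacing <- rep(as.numeric(spacing), length.out = 3)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (is.null(mask)) {
    mask <- array(1, dim(intensities))
  } else {
    if (!identical(dim(mask), dim(intensities))) {
      stop("mask shape must equal intensity shape")
    }
    mask <- array(as.numeric(mask != 0), dim(intensities))
  }
  structure(list(intensities = intensities, spacing = spacing,
                 origin = rep(as.numeric(origin), length.out = 3), mask = mask),
            class = "image_volume")
}

#' 2D image slice
#'
#' @param intensities 2D numeric matrix with values (nominally) in `[0, 1]`.
#' @param spacing pixel spacing in mm (scalar or length 2).
#' @param mask binary matrix of the same shape; default all-valid.
#' @return object of class `image_slice`.
#' @export
image_slice <- function(intensities, spacing = c(1, 1), mask = NULL) {
  intensities <- as.matrix(intensities)
  stopifnot(all(is.finite(intensities)))
  spacing <- rep(as.numeric(spacing), length.out = 2)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (is.null(mask)) {
    mask <- array(1, dim(intensities))
  } else {
    if (!identical(dim(mask), dim(intensities))) {
      stop("mask shape must equal intensity shape")
    }
    mask <- array(as.numeric(mask != 0), dim(intensities))
  }
  structure(list(intensities = intensities, spacing = spacing, mask = mask),
            class = "image_slice")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume ", paste(dim(x$intensities), collapse = " x "),
      " voxels, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm, mask coverage ", format(mean(x$mask), digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
print.image_slice <- function(x, ...) {
  cat("image_slice ", paste(dim(x$intensities), collapse = " x "),
      " px, spacing ", paste(format(x$spacing), collapse = " x "),
      " mm, mask coverage ", format(mean(x$mask), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Physical center of a volume (world coordinates, mm)
#' @param volume an `image_volume`.
#' @return length-3 numeric.
#' @export
volume_center <- function(volume) {
  volume$origin + (dim(volume$intensities) - 1) / 2 * volume$spacing
}

#' Reference sampling grid of a volume
#'
#' Physical coordinates (mm, relative to the volume center) of every voxel
#' center, on the volume's own lattice; the grid that a rigid transform is
#' applied to before resampling.
#'
#' @param volume an `image_volume`.
#' @return a `sampling_grid`: n x 3 matrix of coordinates with a `lattice`
#'   attribute recording the grid shape.
#' @export
make_reference_grid <- function(volume) {
  d <- dim(volume$intensities)
  ax <- lapply(1:3, function(a) ((seq_len(d[a]) - 1) - (d[a] - 1) / 2) * volume$spacing[a])
  pts <- cbind(rep(ax[[1]], times = d[2] * d[3]),
               rep(rep(ax[[2]], each = d[1]), times = d[3]),
               rep(ax[[3]], each = d[1] * d[2]))
  structure(pts, lattice = d, class = c("sampling_grid", class(pts)))
}

#' Transform a sampling grid
#'
#' Maps every grid point through a rigid transform, preserving the lattice
#' organization.
#'
#' @param grid a `sampling_grid` (or any n x 3 coordinate matrix).
#' @param T a `rigid_transform`.
#' @return the mapped grid with the same attributes.
#' @export
transform_grid <- function(grid, T) {
  out <- apply_transform(T, grid)
  attr(out, "lattice") <- attr(grid, "lattice")
  class(out) <- class(grid)
  out
}

# physical (center-relative, mm) -> continuous 0-based voxel coordinates.
# Coordinates within 1e-9 voxel of a lattice plane are snapped onto it, so
# that resampling a volume onto its own lattice is exact despite the
# round-trip through physical units.
phys_to_voxel <- function(volume, pts) {
  d <- dim(volume$intensities)
  v <- sweep(sweep(pts, 2, volume$spacing, "/"), 2, (d - 1) / 2, "+")
  r <- round(v)
  snap <- abs(v - r) < 1e-9
  v[snap] <- r[snap]
  v
}

#' Trilinear interpolation of a volume at physical points
#'
#' Samples the volume's intensities (and mask) at arbitrary physical
#' coordinates relative to the volume center. Points outside the volume
#' extent yield intensity 0 and validity 0. The mask is interpolated with
#' the same trilinear scheme and thresholded at 0.5 to stay binary.
#'
#' @param volume an `image_volume`.
#' @param points n x 3 coordinate matrix (mm, center-relative).
#' @param gradient also return the spatial intensity gradient (per mm).
#' @return list with `value`, `valid` (0/1 in-bounds flag), `mask`
#'   (0/1, in-bounds and interpolated volume mask >= 0.5), and, if requested,
#'   `gx`, `gy`, `gz` in intensity per mm.
#' @export
interpolate <- function(volume, points, gradient = FALSE) {
  points <- matrix(as.numeric(points), ncol = 3)
  v <- phys_to_voxel(volume, points)
  res <- .trilinear_cpp(volume$intensities, volume$mask,
                        v[, 1], v[, 2], v[, 3], gradient)
  out <- list(value = res$value, valid = res$valid,
              mask = as.numeric(res$valid * (res$mask >= 0.5)))
  if (gradient) {
    out$gx <- res$gx / volume$spacing[1]
    out$gy <- res$gy / volume$spacing[2]
    out$gz <- res$gz / volume$spacing[3]
  }
  out
}

#' Resample a volume through a rigid transform
#'
#' Resamples the volume onto its own lattice by inverse mapping: the output
#' voxel at center-relative coordinate `x` takes the input intensity at
#' `T(x)`. The mask is transported identically (trilinear + 0.5 threshold),
#' and out-of-bounds voxels are zero-filled with mask 0.
#'
#' @param volume an `image_volume`.
#' @param T a `rigid_transform`.
#' @return an `image_volume` with the same metadata.
#' @export
transform_volume <- function(volume, T) {
  grid <- make_reference_grid(volume)
  mapped <- transform_grid(grid, T)
  res <- interpolate(volume, mapped)
  d <- dim(volume$intensities)
  image_volume(array(res$value, d), spacing = volume$spacing,
               origin = volume$origin, mask = array(res$mask, d))
}

# Center-relative coordinates of the pixels of a slice lying in its own
# z = 0 plane: n x 3 matrix, x fastest (column-major), z identically 0.
slice_plane_points <- function(slice_shape, slice_spacing) {
  slice_spacing <- rep(as.numeric(slice_spacing), length.out = 2)
  xs <- ((seq_len(slice_shape[1]) - 1) - (slice_shape[1] - 1) / 2) * slice_spacing[1]
  ys <- ((seq_len(slice_shape[2]) - 1) - (slice_shape[2] - 1) / 2) * slice_spacing[2]
  cbind(rep(xs, times = slice_shape[2]),
        rep(ys, each = slice_shape[1]),
        0)
}

#' Extract a 2D slice from a volume at a rigid pose
#'
#' Builds the centered planar grid of the slice frame (its `z = 0` plane),
#' maps it through `T` into volume coordinates, and interpolates. This is the
#' forward resampling step `R[I3D, T]` of slice-to-volume registration; the
#' whole pipeline is smooth in the pose parameters except at the volume
#' boundary, so losses on the extracted slice can be backpropagated to the
#' pose (see [slice_pose_backward()]).
#'
#' @param volume an `image_volume`.
#' @param T a `rigid_transform` mapping slice coordinates into volume
#'   coordinates (both center-relative, mm).
#' @param slice_shape integer length 2, output pixels.
#' @param slice_spacing output pixel spacing in mm (scalar or length 2).
#' @return an `image_slice` with the propagated validity mask; if the plane
#'   misses the volume entirely the slice is all zero, the mask empty, and
#'   attribute `empty` is `TRUE` (with a warning).
#' @export
extract_slice <- function(volume, T, slice_shape, slice_spacing) {
  slice_shape <- as.integer(slice_shape)
  pts <- slice_plane_points(slice_shape, slice_spacing)
  mapped <- apply_transform(T, pts)
  res <- interpolate(volume, mapped)
  sl <- image_slice(matrix(res$value, slice_shape[1], slice_shape[2]),
                    spacing = rep(as.numeric(slice_spacing), length.out = 2),
                    mask = matrix(res$mask, slice_shape[1], slice_shape[2]))
  if (all(sl$mask == 0)) {
    warning("slice plane lies entirely outside the volume")
    attr(sl, "empty") <- TRUE
  }
  sl
}

#' Backpropagate a per-pixel slice loss gradient to the pose
#'
#' Given `dL/dI` for every pixel of a slice extracted with [extract_slice()]
#' at pose `T`, returns the analytic gradient of `L` with respect to the
#' pose: `dL/dt` (per mm) and `dL/dR` (3x3, per rotation-matrix entry).
#' Chain rule: slice pixel `p` at plane coordinate `x_p` samples the volume
#' at `y_p = R x_p + t`, so `dL/dt = sum_p w_p g_p` and
#' `dL/dR = sum_p w_p g_p x_p'` with `g_p` the trilinear intensity gradient.
#' Combine with [sixd_jacobian()] to reach 6D rotation parameters.
#'
#' @param volume an `image_volume`.
#' @param T a `rigid_transform`.
#' @param grad_matrix matrix `dL/dI`, same shape as the extracted slice.
#' @param slice_spacing pixel spacing in mm.
#' @return list with `grad_t` (length 3) and `grad_R` (3x3).
#' @export
slice_pose_backward <- function(volume, T, grad_matrix, slice_spacing) {
  slice_shape <- dim(grad_matrix)
  pts <- slice_plane_points(slice_shape, slice_spacing)
  mapped <- apply_transform(T, pts)
  res <- interpolate(volume, mapped, gradient = TRUE)
  w <- as.numeric(grad_matrix) * res$valid
  G <- cbind(res$gx, res$gy, res$gz)  # n x 3, intensity gradient per mm
  grad_t <- as.numeric(crossprod(G, w))
  grad_R <- crossprod(G * w, pts)     # 3 x 3: sum_p w_p g_p x_p^T
  list(grad_t = grad_t, grad_R = grad_R)
}
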