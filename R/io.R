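# File I/O: NIfTI volumes/slices (via RNifti, spacing preserved in pixdim)
# and the JSON transform format defined in geometry.R.

#' Write an image volume or slice to NIfTI
#'
#' Volumes are written as 3D NIfTI with their spacing in `pixdim`; slices
#' as single-slice 3D images (third dimension 1). The origin of volumes is
#' stored in the sform translation. The mask, if requested, is written next
#' to the image with suffix `_mask`.
#'
#' @param image an `image_volume` or `image_slice`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param with_mask also write `<path minus extension>_mask.nii(.gz)`.
#' @return the path, invisibly.
#' @export
write_image_nifti <- function(image, path, with_mask = FALSE) {
  if (inherits(image, "image_slice")) {
    arr <- image$intensities
    spac <- image$spacing
    msk <- image$mask
  } else if (inherits(image, "image_volume")) {
    arr <- image$intensities
    spac <- image$spacing
    msk <- image$mask
  } else {
    stop("expected an image_volume or image_slice")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spac
  RNifti::writeNifti(img, path)
  if (with_mask) {
    mimg <- RNifti::asNifti(msk)
    RNifti::pixdim(mimg) <- spac
    RNifti::writeNifti(mimg, mask_path(path))
  }
  invisible(path)
}

mask_path <- function(path) {
  sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
}

#' Read an image volume or slice from NIfTI
#'
#' A 2D image (or one with a trailing singleton dimension) is returned as an
#' `image_slice`; anything else as an `image_volume`. A mask file with
#' suffix `_mask` (as written by [write_image_nifti()]) is picked up
#' automatically.
#'
#' @param path NIfTI file path.
#' @return an `image_volume` or `image_slice`.
#' @export
read_image_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.numeric(arr), dim(arr))   # drop niftiImage attributes
  d <- dim(arr)
  if (length(d) > 2 && d[length(d)] == 1) {
    arr <- array(arr, d[1:2])
    d <- dim(arr)
  }
  spac <- RNifti::pixdim(img)
  mp <- mask_path(path)
  msk <- if (mp != path && file.exists(mp)) {
    m <- as.array(RNifti::readNifti(mp))
    array(as.numeric(m), d)
  } else {
    NULL
  }
  if (length(d) == 2) {
    image_slice(arr, spacing = spac[1:2], mask = msk)
  } else {
    image_volume(arr, spacing = spac[1:3], mask = msk)
  }
}

#' Save network weights and configuration
#'
#' Weights are serialized as JSON (flat numeric vector plus the
#' configuration needed to rebuild the parameter tree), a plain-text
#' checkpoint format that survives text-only pipelines.
#'
#' @param weights a `network_weights` object.
#' @param cfg the matching [network_config()].
#' @param path output `.json` path.
#' @export
write_weights <- function(weights, cfg, path) {
  obj <- list(config = unclass(cfg),
              params = flatten_params(weights))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load network weights saved by [write_weights()]
#' @param path `.json` checkpoint path.
#' @return list with `weights` and `cfg`.
#' @export
read_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(network_config, obj$config[names(obj$config) %in%
                                              names(formals(network_config))])
  skel <- init_network(cfg)
  list(weights = unflatten_params(as.numeric(obj$params), skel), cfg = cfg)
}
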