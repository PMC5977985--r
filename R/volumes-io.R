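#' Volume containers and NIfTI input/output
#'
#' The pipeline consumes structural brain volumes that are already registered
#' to a common space and (optionally) segmented into tissue probability maps;
#' no resampling or registration is performed here. A `volume_grid` is a plain
#' 3D intensity array plus voxel geometry, the in-memory counterpart of one
#' NIfTI-1 image.
#'
#' @param intensities 3D numeric array of voxel intensities (all finite).
#' @param voxel_size_mm length-3 positive numeric, voxel edge lengths in mm.
#' @param channel one of `"whole_brain"`, `"GM"`, `"WM"`.
#' @param affine 4x4 voxel-to-world matrix; default is a diagonal scaling by
#'   the voxel sizes.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(intensities, voxel_size_mm = c(1, 1, 1),
                        channel = c("whole_brain", "GM", "WM"),
                        affine = NULL) {
  channel <- match.arg(channel)
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop_arg("intensities must be a 3D array")
  }
  if (!all(is.finite(intensities))) stop_arg("intensities must all be finite")
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0)) {
    stop_arg("voxel_size_mm must be 3 positive reals")
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  structure(
    list(intensities = intensities,
         voxel_size_mm = as.numeric(voxel_size_mm),
         channel = channel,
         affine = affine),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s, %s voxels, %s mm\n",
              x$channel,
              paste(dim(x$intensities), collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x")))
  invisible(x)
}

#' Read a 3D NIfTI-1 volume
#'
#' @param path path to a NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param channel channel tag to attach (`"whole_brain"`, `"GM"` or `"WM"`);
#'   NIfTI headers do not carry a tissue label, so the caller supplies it.
#' @return a [volume_grid()].
#' @export
read_volume <- function(path, channel = "whole_brain") {
  if (!file.exists(path)) stop_arg("no such NIfTI file: ", path)
  img <- tryCatch(
    RNifti::readNifti(path),
    error = function(e) stop_arg("failed to read NIfTI file '", path, "': ",
                                 conditionMessage(e))
  )
  d <- dim(img)
  if (length(d) != 3L) {
    stop_arg("expected a 3D volume, got ", length(d), "D in '", path, "'")
  }
  pix <- RNifti::pixdim(img)[seq_len(3L)]
  volume_grid(array(as.numeric(img), dim = d),
              voxel_size_mm = pix,
              channel = channel,
              affine = RNifti::xform(img))
}

#' Write a volume as NIfTI-1
#'
#' @param v a [volume_grid()].
#' @param path output path; `.nii` writes uncompressed, `.nii.gz` compressed.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_grid"))
  img <- RNifti::asNifti(v$intensities)
  RNifti::pixdim(img) <- v$voxel_size_mm
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Half-sample symmetric reflection of 0-based index i into [0, d).
reflect_index <- function(i, d) {
  while (any(bad <- i < 0L | i >= d)) {
    i[bad & i < 0L] <- -i[bad & i < 0L] - 1L
    bad <- i >= d
    i[bad] <- 2L * d - 1L - i[bad]
  }
  i
}

# Dense d x d one-axis Gaussian convolution matrix with reflecting boundary.
# The kernel is the normalized discrete Gaussian sampled at integer offsets
# out to 4 sigma; reflection folds out-of-grid mass back so the matrix has
# unit column sums (total intensity is conserved).
gaussian_axis_matrix <- function(d, sigma_vox) {
  if (sigma_vox <= 0) return(diag(d))
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  g <- stats::dnorm(-r:r, sd = sigma_vox)
  g <- g / sum(g)
  K <- matrix(0, d, d)
  for (j in seq_len(d)) {
    src <- reflect_index((j - 1L) + (-r:r), d) + 1L
    for (m in seq_along(src)) K[j, src[m]] <- K[j, src[m]] + g[m]
  }
  K
}

apply_along_axis <- function(A, K, axis) {
  p <- seq_along(dim(A))
  perm <- c(axis, p[-axis])
  B <- aperm(A, perm)
  db <- dim(B)
  B <- array(K %*% matrix(B, nrow = db[1L]), dim = db)
  aperm(B, order(perm))
}

# Smooth a bare 3D array with an isotropic Gaussian of the given FWHM (mm),
# given per-axis voxel sizes. Exposed internally so batch smoothing of
# flattened cohort matrices can share the per-axis kernel matrices.
smooth_array <- function(arr, fwhm_mm, voxel_size_mm) {
  if (fwhm_mm == 0) return(arr)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  for (axis in 1:3) {
    K <- gaussian_axis_matrix(dim(arr)[axis], sigma_mm / voxel_size_mm[axis])
    arr <- apply_along_axis(arr, K, axis)
  }
  arr
}

#' Gaussian smoothing of a volume
#'
#' Separable 3D Gaussian convolution. The per-axis kernel standard deviation
#' in voxels is `fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm[axis]`; the
#' discrete kernel is normalized to unit sum and the boundary is handled by
#' reflection, so total intensity is conserved. `fwhm_mm = 0` returns the
#' input unchanged.
#'
#' @param v a [volume_grid()].
#' @param fwhm_mm non-negative isotropic full width at half maximum, in mm.
#' @return a smoothed [volume_grid()].
#' @export
smooth_volume <- function(v, fwhm_mm) {
  stopifnot(inherits(v, "volume_grid"))
  assert_scalar_number(fwhm_mm, "fwhm_mm")
  if (fwhm_mm < 0) stop_arg("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(v)
  v$intensities <- smooth_array(v$intensities, fwhm_mm, v$voxel_size_mm)
  v
}

#' Flatten masked voxels into a feature vector
#'
#' Voxel ordering is fixed and documented: R column-major order, i.e. the
#' FIRST axis varies fastest. The same ordering is used for every subject, so
#' feature index j always addresses the same voxel, and [unflatten_masked()]
#' inverts the operation on the masked support.
#'
#' @param v a [volume_grid()] or bare 3D array.
#' @param mask logical 3D array congruent with `v` (`TRUE` = include); at
#'   least one voxel must be included.
#' @return numeric vector of masked intensities.
#' @export
flatten_masked <- function(v, mask) {
  arr <- if (inherits(v, "volume_grid")) v$intensities else v
  if (!is.array(arr) || length(dim(arr)) != 3L) stop_arg("v must be 3D")
  if (!identical(dim(arr), dim(mask))) {
    stop_arg("mask shape ", paste(dim(mask), collapse = "x"),
             " does not match volume shape ", paste(dim(arr), collapse = "x"))
  }
  keep <- as.logical(mask)
  if (!any(keep)) stop_arg("mask selects no voxels")
  as.numeric(arr)[keep]
}

#' Restore a flat masked vector into a 3D grid
#'
#' @param values numeric vector as produced by [flatten_masked()].
#' @param mask the logical mask used to flatten.
#' @param fill value for voxels outside the mask.
#' @return 3D numeric array with `dim(mask)`.
#' @export
unflatten_masked <- function(values, mask, fill = 0) {
  keep <- as.logical(mask)
  if (length(values) != sum(keep)) {
    stop_arg("length(values) must equal the number of masked voxels")
  }
  out <- array(fill, dim = dim(mask))
  out[keep] <- values
  out
}
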