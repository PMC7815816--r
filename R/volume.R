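#' Create a density volume
#'
#' Lightweight container for a 3D scalar field on a regular voxel grid: the
#' data array, the voxel size in mm, and a voxel-to-world affine. Used for
#' gray-matter density inputs, masks, PET volumes and metric maps alike.
#'
#' @param data 3D numeric array.
#' @param voxel_size voxel edge length(s) in mm; length 1 or 3.
#' @param affine 4x4 voxel-to-world matrix mapping 0-based voxel indices to
#'   world mm. Defaults to a diagonal scaling by `voxel_size`.
#' @return An object of class `density_volume`: a list with elements
#'   `data`, `voxel_size` (length 3) and `affine`.
#' @export
#' @examples
#' v <- density_volume(array(runif(27), c(3, 3, 3)), voxel_size = 2)
#' dim(v$data)
density_volume <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(!is.finite(data)))
    stop("volume contains non-finite values")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 affine = affine),
            class = "density_volume")
}

#' @export
print.density_volume <- function(x, ...) {
  cat("density_volume:", paste(dim(x$data), collapse = " x "),
      "voxels,", paste(signif(x$voxel_size, 3), collapse = " x "), "mm\n")
  cat("  range: [", signif(min(x$data), 4), ",", signif(max(x$data), 4), "]\n")
  invisible(x)
}

# Coerce arrays / RNifti images to density_volume.
as_density_volume <- function(x, voxel_size = c(1, 1, 1)) {
  if (inherits(x, "density_volume")) return(x)
  if (inherits(x, "niftiImage")) {
    pd <- RNifti::pixdim(x)[1:3]
    aff <- matrix(as.numeric(RNifti::xform(x)), 4, 4)
    arr <- as.array(x)
    attributes(arr) <- list(dim = dim(arr))
    return(density_volume(arr, voxel_size = pd, affine = aff))
  }
  if (is.array(x) && length(dim(x)) == 3L)
    return(density_volume(x, voxel_size = voxel_size))
  stop("cannot interpret input as a 3D volume")
}

#' Read a NIfTI volume
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A [density_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  as_density_volume(RNifti::readNifti(path))
}

#' Write a volume to NIfTI
#'
#' @param vol a [density_volume()] or 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_density_volume(vol)
  im <- RNifti::asNifti(vol$data)
  RNifti::pixdim(im) <- vol$voxel_size
  ok <- tryCatch({
    RNifti::writeNifti(im, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop("failed to write NIfTI volume to: ", path)
  invisible(path)
}

#' Convert voxel indices to world coordinates
#'
#' @param ijk matrix (or vector) of 0-based voxel indices, one row per voxel.
#' @param affine 4x4 voxel-to-world matrix.
#' @return Matrix of world-space mm coordinates.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- rbind(ijk)
  xyz <- cbind(ijk, 1) %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}
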