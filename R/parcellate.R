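#' Tile a masked volume into 3x3x3-voxel cube nodes
#'
#' Network nodes are small cubic regions of interest: non-overlapping
#' `cube_edge`^3-voxel cubes (default 3x3x3, i.e. 6 mm per side at 2 mm
#' voxels) tiling the bounding box of the mask. A cube is retained when the
#' fraction of its voxels inside the mask is at least `min_inside_fraction`
#' (default 1: fully inside, so edge cubes dominated by non-GM zeros are
#' dropped). Node order is the raster order of cube origins (first axis
#' fastest), which is deterministic and identical across subjects sharing a
#' grid and mask.
#'
#' @param volume a [density_volume()] (or 3D array) of gray-matter density.
#' @param mask binary volume on the same grid; `NULL` means all voxels.
#' @param min_inside_fraction minimum in-mask voxel fraction for a cube to
#'   become a node, in (0, 1].
#' @param cube_edge cube edge length in voxels (default 3).
#' @return An object of class `cube_nodes`: list with
#'   \describe{
#'     \item{values}{n x 27 matrix, one row per node, raster-ordered cube
#'       densities}
#'     \item{centers}{n x 3 matrix of 0-based center voxel indices}
#'     \item{origins}{n x 3 matrix of 0-based cube origin voxel indices}
#'     \item{degenerate}{logical: zero-variance cubes (kept as nodes; they
#'       receive similarity 0 to all partners)}
#'     \item{voxel_size, affine, dim}{grid geometry carried through}
#'   }
#' @export
parcellate_cubes <- function(volume, mask = NULL, min_inside_fraction = 1,
                             cube_edge = 3L) {
  volume <- as_density_volume(volume)
  dm <- dim(volume$data)
  if (is.null(mask)) {
    mk <- array(TRUE, dm)
  } else {
    mask <- as_density_volume(mask)
    if (!all(dim(mask$data) == dm))
      stop("mask grid does not match volume grid")
    mk <- mask$data != 0
  }
  if (min_inside_fraction <= 0 || min_inside_fraction > 1)
    stop("`min_inside_fraction` must be in (0, 1]")
  ce <- as.integer(cube_edge)
  if (!any(mk)) stop("empty parcellation: mask contains no voxels")

  # bounding box of the mask (1-based)
  idx <- which(mk, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  ncube <- (hi - lo + 1L) %/% ce
  if (any(ncube < 1L))
    stop("empty parcellation: mask bounding box smaller than one cube")

  origins <- as.matrix(expand.grid(
    lo[1] + ce * (seq_len(ncube[1]) - 1L),
    lo[2] + ce * (seq_len(ncube[2]) - 1L),
    lo[3] + ce * (seq_len(ncube[3]) - 1L)))
  nvox <- ce^3
  keep <- logical(nrow(origins))
  vals <- matrix(0, nrow(origins), nvox)
  for (r in seq_len(nrow(origins))) {
    o <- origins[r, ]
    sl <- list(o[1]:(o[1] + ce - 1L), o[2]:(o[2] + ce - 1L),
               o[3]:(o[3] + ce - 1L))
    frac <- mean(mk[sl[[1]], sl[[2]], sl[[3]]])
    if (frac >= min_inside_fraction) {
      keep[r] <- TRUE
      vals[r, ] <- as.vector(volume$data[sl[[1]], sl[[2]], sl[[3]]])
    }
  }
  if (!any(keep)) stop("empty parcellation: no cube meets `min_inside_fraction`")

  origins <- origins[keep, , drop = FALSE]
  vals <- vals[keep, , drop = FALSE]
  centers0 <- origins - 1L + (ce %/% 2L) # 0-based center voxel
  degen <- apply(vals, 1, function(v) var(v) == 0)
  structure(list(values = vals,
                 centers = unname(centers0),
                 origins = unname(origins - 1L),
                 degenerate = degen,
                 cube_edge = ce,
                 voxel_size = volume$voxel_size,
                 affine = volume$affine,
                 dim = dm),
            class = "cube_nodes")
}

#' @export
print.cube_nodes <- function(x, ...) {
  cat("cube_nodes:", nrow(x$values), "nodes of", x$cube_edge, "^3 voxels (",
      signif(x$cube_edge * x$voxel_size[1], 3), "mm side );",
      sum(x$degenerate), "degenerate\n")
  invisible(x)
}
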