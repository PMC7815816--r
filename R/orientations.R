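#' Orientation maps of a 3x3x3 cube
#'
#' Enumerates index maps realizing orientation transforms of a cube of 27
#' voxels stored in raster order (first axis fastest). The default
#' `"orthogonal"` set is the full symmetry group of the cube: 24 proper
#' rotations, doubled to 48 by reflection. These are exact value
#' permutations, so Pearson correlations against transformed cubes are
#' well defined without interpolation.
#'
#' The optional `"rot45"` set adds rotations in 45-degree steps about each
#' grid axis, realized by nearest-neighbour resampling of the rotated
#' coordinates (off-lattice corners snap back to the lattice). Those maps
#' are not permutations — some source voxels are duplicated and others
#' dropped — and are provided for fidelity experiments only.
#'
#' @param set `"orthogonal"` (48 exact symmetries, default) or `"rot45"`
#'   (orthogonal set plus nearest-neighbour 45-degree rotations composed
#'   with axis reflections).
#' @param reflections include improper transforms (reflections)? Default
#'   `TRUE`.
#' @return Integer matrix with 27 rows; column `m` maps a value vector `v`
#'   to its transformed version `v[maps[, m]]`. The first column is the
#'   identity.
#' @export
#' @examples
#' maps <- cube_orientations()
#' ncol(maps)  # 48
cube_orientations <- function(set = c("orthogonal", "rot45"),
                              reflections = TRUE) {
  set <- match.arg(set)
  coords <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  ckey <- function(m) apply(round(m), 1L, paste, collapse = ",")
  base_key <- ckey(coords)

  axis_perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                      c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  maps <- list()
  for (p in seq_len(nrow(axis_perms)))
    for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
      R <- matrix(0, 3, 3)
      s <- c(sx, sy, sz)
      for (r in 1:3) R[r, axis_perms[p, r]] <- s[r]
      if (!reflections && round(det(R)) < 0) next
      maps[[length(maps) + 1L]] <- match(ckey(coords %*% t(R)), base_key)
    }

  if (set == "rot45") {
    rot_about <- function(axis, theta) {
      ct <- cos(theta); st <- sin(theta)
      R2 <- matrix(c(ct, -st, st, ct), 2, 2, byrow = TRUE)
      R <- diag(3)
      oth <- setdiff(1:3, axis)
      R[oth, oth] <- R2
      R
    }
    refl <- list()
    for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
      F <- diag(c(sx, sy, sz))
      refl[[length(refl) + 1L]] <- match(ckey(coords %*% t(F)), base_key)
    }
    for (axis in 1:3)
      for (theta in pi / 4 * c(1, 3, 5, 7)) {
        R <- rot_about(axis, theta)
        src <- coords %*% t(R)
        src <- pmin(pmax(round(src), -1), 1) # snap to lattice
        m_rot <- match(ckey(src), base_key)
        for (m_ref in refl)
          maps[[length(maps) + 1L]] <- m_rot[m_ref]
      }
  }

  out <- unique(do.call(cbind, lapply(maps, as.integer)), MARGIN = 2)
  # identity first, for readability
  id <- which(apply(out, 2, function(m) all(m == 1:27)))[1]
  out[, c(id, setdiff(seq_len(ncol(out)), id)), drop = FALSE]
}
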