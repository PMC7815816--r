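# Build a cube_nodes object directly from a values matrix (n x 27), for
# tests that construct node sets without a volume.
make_nodes <- function(values, voxel_size = 2) {
  n <- nrow(values)
  centers <- cbind(seq_len(n) * 3 - 2, 1L, 1L)
  structure(list(values = values,
                 centers = centers,
                 origins = centers - 1L,
                 degenerate = apply(values, 1, function(v) var(v) == 0),
                 cube_edge = 3L,
                 voxel_size = rep(voxel_size, 3),
                 affine = diag(c(rep(voxel_size, 3), 1)),
                 dim = c(3L * n, 3L, 3L)),
            class = "cube_nodes")
}

# node set with `n_pairs` planted perfect-similarity pairs (exact copies)
# followed by independent-noise nodes; rows 2i-1 and 2i are the copies.
planted_pair_nodes <- function(n_pairs, n_extra = 0) {
  vals <- matrix(rnorm((2 * n_pairs + n_extra) * 27), ncol = 27)
  for (i in seq_len(n_pairs)) vals[2 * i, ] <- vals[2 * i - 1, ]
  make_nodes(vals)
}
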