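# Center each row and scale to unit L2 norm, so that the inner product of
# two standardized rows is exactly their Pearson correlation. Zero-variance
# rows are set to 0 (degenerate: correlate 0 with everything).
standardize_rows <- function(V) {
  ctr <- V - rowMeans(V)
  nrm <- sqrt(rowSums(ctr^2))
  z <- ctr / ifelse(nrm > 0, nrm, 1)
  z[nrm == 0, ] <- 0
  z
}

maps_are_permutations <- function(maps) {
  all(apply(maps, 2, function(m) identical(sort(m), seq_len(nrow(maps)))))
}

#' Orientation-maximized similarity of two cube nodes
#'
#' The maximum Pearson correlation between one cube's 27 densities and
#' every orientation transform (rotation/reflection) of the other's. With
#' the default orientation set (the 48 exact cube symmetries, a group
#' closed under inversion) the measure is symmetric in its arguments; for
#' non-group sets (e.g. `"rot45"` nearest-neighbour maps) both directions
#' are scanned so symmetry always holds.
#'
#' @param a,b numeric vectors of cube densities (same length, matching the
#'   orientation maps' row count).
#' @param orientations index-map matrix from [cube_orientations()].
#' @return Correlation in \[-1, 1\]. Zero-variance cubes are degenerate and
#'   return 0 (they can never exceed a positive edge threshold).
#' @export
#' @examples
#' v <- rnorm(27)
#' maps <- cube_orientations()
#' max_similarity(v, v[maps[, 10]])  # 1: orientation invariance
max_similarity <- function(a, b, orientations = cube_orientations()) {
  stopifnot(length(a) == nrow(orientations), length(b) == length(a))
  if (var(a) == 0 || var(b) == 0) return(0)
  za <- standardize_rows(rbind(a))[1, ]
  zb <- standardize_rows(rbind(b))[1, ]
  m1 <- max(apply(orientations, 2, function(m) sum(za * zb[m])))
  m2 <- max(apply(orientations, 2, function(m) sum(zb * za[m])))
  min(max(m1, m2), 1)
}

#' Similarity matrix over all cube-node pairs
#'
#' Fills every unordered node pair with the orientation-maximized Pearson
#' correlation. With a permutation orientation set the computation runs as
#' one standardized cross-product per orientation (BLAS), taking the
#' element-wise maximum; the result is symmetrized exactly by copying the
#' upper triangle. Degenerate (zero-variance) nodes get similarity 0 to all
#' partners; the diagonal is fixed at 1.
#'
#' @param nodes a `cube_nodes` object from [parcellate_cubes()].
#' @param orientations index-map matrix from [cube_orientations()].
#' @return Object of class `similarity_matrix`: a symmetric numeric matrix
#'   in \[-1, 1\] with attributes `centers`, `affine`, `degenerate`.
#' @export
similarity_matrix <- function(nodes, orientations = cube_orientations()) {
  V <- nodes$values
  n <- nrow(V)
  if (sum(!nodes$degenerate) < 2)
    stop("need at least 2 non-degenerate nodes")
  Z <- standardize_rows(V)
  if (maps_are_permutations(orientations)) {
    S <- matrix(-Inf, n, n)
    for (m in seq_len(ncol(orientations)))
      S <- pmax(S, tcrossprod(Z, Z[, orientations[, m], drop = FALSE]))
  } else {
    S <- matrix(-Inf, n, n)
    for (m in seq_len(ncol(orientations))) {
      M <- tcrossprod(Z, Z[, orientations[, m], drop = FALSE])
      S <- pmax(S, M, t(M))
    }
  }
  S[S > 1] <- 1
  S[S < -1] <- -1
  S[nodes$degenerate, ] <- 0
  S[, nodes$degenerate] <- 0
  # exact symmetry: compute once per unordered pair (upper triangle wins)
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  diag(S) <- 1
  structure(S, class = c("similarity_matrix", "matrix"),
            centers = nodes$centers, affine = nodes$affine,
            degenerate = nodes$degenerate)
}

#' Empirical null distribution of orientation-maximized similarity
#'
#' Samples the null: pick a random pair of (non-degenerate) nodes, randomly
#' permute the 27 values of one member — destroying spatial correspondence
#' while preserving each cube's value distribution — and record the
#' orientation-maximized correlation. The resulting sample is the reference
#' against which observed similarities are converted to empirical p-values.
#'
#' @param nodes a `cube_nodes` object.
#' @param n_samples number of null draws (>= 1000).
#' @param seed RNG seed (restored on exit).
#' @param orientations index-map matrix from [cube_orientations()].
#' @return Object of class `null_distribution`: list with `samples`,
#'   `n_samples`, `seed`.
#' @export
empirical_null <- function(nodes, n_samples = 10000L, seed = 1L,
                           orientations = cube_orientations()) {
  if (n_samples < 1000L) stop("`n_samples` must be at least 1000")
  ok <- which(!nodes$degenerate)
  if (length(ok) < 2L) stop("need at least 2 non-degenerate nodes")
  Z <- standardize_rows(nodes$values)
  samples <- with_seed(seed, {
    ii <- sample(ok, n_samples, replace = TRUE)
    jj <- sample(ok, n_samples, replace = TRUE)
    clash <- which(jj == ii)
    while (length(clash)) {
      jj[clash] <- sample(ok, length(clash), replace = TRUE)
      clash <- clash[jj[clash] == ii[clash]]
    }
    Za <- Z[ii, , drop = FALSE]
    Zb <- Z[jj, , drop = FALSE]
    nv <- ncol(Z)
    is_perm <- maps_are_permutations(orientations)
    # independent random permutation per sampled pair
    Zp <- matrix(0, n_samples, nv)
    for (r in seq_len(n_samples)) Zp[r, ] <- Zb[r, sample.int(nv)]
    best <- rep(-Inf, n_samples)
    for (m in seq_len(ncol(orientations))) {
      best <- pmax(best, rowSums(Za * Zp[, orientations[, m], drop = FALSE]))
      if (!is_perm)
        best <- pmax(best, rowSums(Zp * Za[, orientations[, m], drop = FALSE]))
    }
    pmin(best, 1)
  })
  structure(list(samples = samples, n_samples = n_samples, seed = seed),
            class = "null_distribution")
}

#' FDR edge threshold from an empirical null
#'
#' Converts each off-diagonal similarity to an empirical p-value — the
#' fraction of null samples at least as large, with (r+1)/(n+1) smoothing
#' so no p-value is exactly zero; similarities beyond the observed null
#' range get a continuous tail p-value from a peaks-over-threshold
#' generalized Pareto fit to the null's upper 1%, never larger than the
#' discrete floor — applies Benjamini-Hochberg across all
#' unordered pairs jointly, and returns the cut point separating the
#' significant pairs from the rest: the largest similarity *not* declared
#' significant at level `q` (p-values are monotone in similarity, so the
#' significant set is exactly the strictly-greater values). Binarizing at
#' this threshold with the strict greater-than rule therefore retains
#' every significant pair and ensures an expected proportion of spurious
#' connections of at most `q` (a 5% chance of spurious correlations at
#' the default `q = 0.05`).
#'
#' @param sim a `similarity_matrix`.
#' @param null a `null_distribution` from [empirical_null()].
#' @param q FDR level in (0, 1); default 0.05.
#' @return The threshold value (scalar). `+Inf` when no pair is significant
#'   (empty graph). Attributes: `n_significant`, `min_significant`, `q`.
#' @export
fdr_edge_threshold <- function(sim, null, q = 0.05) {
  if (!inherits(null, "null_distribution") || length(null$samples) == 0)
    stop("`null` must be a non-empty null_distribution")
  if (q <= 0 || q >= 1) stop("`q` must be in (0, 1)")
  s <- sim[upper.tri(sim)]
  ns <- sort(null$samples)
  nn <- length(ns)
  n_ge <- nn - findInterval(s, ns, left.open = TRUE) # null samples >= s
  p <- (n_ge + 1) / (nn + 1)
  # Similarities beyond the observed null range would all share the floor
  # p-value 1/(n+1); with hundreds of thousands of pairs that resolution
  # is coarser than the BH line and the decision becomes an all-or-nothing
  # function of the null's sample maximum. Extend the null's upper tail
  # with a peaks-over-threshold generalized Pareto fit (method of moments,
  # exceedances over the 99th percentile) so such pairs get a continuous,
  # monotone p-value; inside the observed range the discrete estimator is
  # used unchanged.
  above <- s > ns[nn]
  if (any(above)) {
    u <- ns[floor(0.99 * nn)]
    exc <- ns[ns > u] - u
    if (length(exc) >= 20 && var(exc) > 0) {
      m1 <- mean(exc)
      v <- var(exc)
      xi <- min(0.5 * (1 - m1^2 / v), 0.4)
      beta <- 0.5 * m1 * (m1^2 / v + 1)
      y <- s[above] - u
      surv <- if (abs(xi) < 1e-8) exp(-y / beta) else {
        arg <- 1 + xi * y / beta
        ifelse(arg <= 0, 0, arg^(-1 / xi))
      }
      p[above] <- pmin(p[above],
                       pmax((length(exc) / nn) * surv, 1e-16))
    }
  }
  sig <- p.adjust(p, method = "BH") <= q
  thr <- if (!any(sig)) Inf else if (all(sig)) -1 else max(s[!sig])
  structure(thr, n_significant = sum(sig),
            min_significant = if (any(sig)) min(s[sig]) else Inf, q = q)
}

#' Binarize a similarity matrix into an adjacency matrix
#'
#' Strict rule: a correlation greater than the threshold is an edge (1),
#' lower-or-equal is no edge (0). The diagonal is forced to 0 (no
#' self-loops).
#'
#' @param sim a `similarity_matrix` (or symmetric numeric matrix).
#' @param threshold finite value or `+Inf` (empty graph).
#' @return Binary symmetric integer matrix of class `adjacency_matrix` with
#'   node `centers`/`affine` carried through when present.
#' @export
binarize <- function(sim, threshold) {
  stopifnot(length(threshold) == 1L, !is.na(threshold))
  A <- (unclass(sim) > as.numeric(threshold)) * 1L
  diag(A) <- 0L
  structure(A, class = c("adjacency_matrix", "matrix"),
            centers = attr(sim, "centers"), affine = attr(sim, "affine"),
            threshold = as.numeric(threshold))
}
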