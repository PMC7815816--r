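test_that("a node correlates 1 with itself and any orientation transform of itself", {
  set.seed(11)
  v <- rnorm(27)
  maps <- cube_orientations()
  expect_equal(max_similarity(v, v), 1)
  for (m in seq_len(ncol(maps)))
    expect_equal(max_similarity(v, v[maps[, m]]), 1)
})

test_that("max similarity equals exhaustive orientation enumeration", {
  # worked case: values 1..27 with two voxels swapped; expected value by
  # direct cor() over every orientation, both directions
  a <- as.numeric(1:27)
  b <- a
  b[c(3, 19)] <- b[c(19, 3)]
  maps <- cube_orientations()
  expected <- max(vapply(seq_len(ncol(maps)), function(m)
    max(cor(a, b[maps[, m]]), cor(b, a[maps[, m]])), numeric(1)))
  expect_equal(max_similarity(a, b), expected)
  expect_lt(expected, 1)

  # random pairs: symmetry and agreement with enumeration
  set.seed(7)
  for (r in 1:10) {
    x <- rnorm(27)
    y <- rnorm(27)
    expected <- max(vapply(seq_len(ncol(maps)), function(m)
      cor(x, y[maps[, m]]), numeric(1)))
    expect_equal(max_similarity(x, y), expected)
    expect_equal(max_similarity(x, y), max_similarity(y, x))
  }
})

test_that("degenerate zero-variance cubes get similarity 0", {
  expect_equal(max_similarity(rep(1, 27), rnorm(27)), 0)
})

test_that("similarity matrix is symmetric, bounded, unit diagonal, and matches pairwise calls", {
  set.seed(21)
  nodes <- make_nodes(matrix(rnorm(8 * 27), ncol = 27))
  S <- similarity_matrix(nodes)
  expect_true(isSymmetric(unclass(S)))
  expect_true(all(S >= -1 & S <= 1))
  expect_equal(unname(diag(S)), rep(1, 8))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(S[i, j],
                 max_similarity(nodes$values[i, ], nodes$values[j, ]),
                 tolerance = 1e-12)
})

test_that("transforming every node by one orientation leaves the similarity matrix unchanged", {
  set.seed(31)
  vals <- matrix(rnorm(6 * 27), ncol = 27)
  maps <- cube_orientations()
  S0 <- unclass(similarity_matrix(make_nodes(vals)))
  for (m in c(2, 13, 29, 48)) {
    vals_t <- vals[, maps[, m]]
    St <- unclass(similarity_matrix(make_nodes(vals_t)))
    expect_equal(St, S0, tolerance = 1e-10)
  }
})

test_that("degenerate nodes propagate zero rows through the similarity matrix", {
  set.seed(5)
  vals <- matrix(rnorm(5 * 27), ncol = 27)
  vals[3, ] <- 2
  S <- similarity_matrix(make_nodes(vals))
  expect_equal(unname(S[3, -3]), rep(0, 4))
  expect_equal(S[3, 3], 1)
})

test_that("the empirical null is deterministic in the seed and lives in [-1, 1]", {
  set.seed(77)
  nodes <- make_nodes(matrix(rnorm(10 * 27), ncol = 27))
  n1 <- empirical_null(nodes, n_samples = 1000, seed = 4)
  n2 <- empirical_null(nodes, n_samples = 1000, seed = 4)
  n3 <- empirical_null(nodes, n_samples = 1000, seed = 5)
  expect_identical(n1$samples, n2$samples)
  expect_false(identical(n1$samples, n3$samples))
  expect_true(all(n1$samples >= -1 & n1$samples <= 1))
  expect_error(empirical_null(nodes, n_samples = 500, seed = 1), "1000")
})

test_that("an extreme observed pair survives FDR thresholding", {
  set.seed(13)
  nodes <- planted_pair_nodes(1, n_extra = 18)
  S <- similarity_matrix(nodes)
  null <- empirical_null(nodes, n_samples = 10000, seed = 2)
  thr <- fdr_edge_threshold(S, null, q = 0.05)
  expect_lt(thr, 1)
  A <- binarize(S, thr)
  expect_equal(A[1, 2], 1L)
})

test_that("FDR threshold agrees with an independent BH computation", {
  set.seed(19)
  nodes <- planted_pair_nodes(3, n_extra = 14)
  S <- similarity_matrix(nodes)
  null <- empirical_null(nodes, n_samples = 2000, seed = 8)
  q <- 0.1
  thr <- fdr_edge_threshold(S, null, q = q)
  # independent route: explicit empirical p per pair + stats::p.adjust
  s <- S[upper.tri(S)]
  p <- vapply(s, function(x) (sum(null$samples >= x) + 1) /
                (length(null$samples) + 1), numeric(1))
  sig <- p.adjust(p, "BH") <= q
  expect_equal(as.numeric(thr), max(s[!sig]))
  expect_equal(attr(thr, "min_significant"), min(s[sig]))
  expect_equal(attr(thr, "n_significant"), sum(sig))
  # strict binarization retains exactly the significant pairs
  A <- binarize(S, thr)
  expect_equal(sum(A) / 2, sum(sig))
})

test_that("no significant pair yields an infinite threshold and an empty graph", {
  set.seed(23)
  nodes <- make_nodes(matrix(rnorm(12 * 27), ncol = 27))
  S <- similarity_matrix(nodes)
  null <- empirical_null(nodes, n_samples = 2000, seed = 3)
  thr <- fdr_edge_threshold(S, null, q = 1e-4)
  expect_identical(as.numeric(thr), Inf)
  expect_equal(sum(binarize(S, thr)), 0L)
})

test_that("binarization applies the strict greater-than rule", {
  S <- diag(3)
  S[1, 2] <- S[2, 1] <- 0.9
  S[1, 3] <- S[3, 1] <- 0.5
  S[2, 3] <- S[3, 2] <- 0.7
  A <- binarize(S, 0.6)
  expect_equal(unclass(A), matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3),
               ignore_attr = TRUE)
  # ties are not edges (strictly greater), diagonal is forced to zero
  expect_equal(sum(binarize(S, 0.9)), 0L)
  expect_equal(unname(diag(binarize(S, -2))), rep(0L, 3))
  expect_equal(sum(binarize(S, -2)), 6L) # complete graph minus diagonal
})
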