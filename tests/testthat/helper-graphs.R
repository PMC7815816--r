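# Independent brute-force graph-metric oracles via adjacency-matrix powers:
# walks of minimal length are exactly the shortest paths, so (A^d)[i, j]
# counts shortest i-j paths when d is the BFS distance. Deliberately
# different machinery from the package's BFS/Brandes implementations.

bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  P <- diag(n)
  powers <- list(P)
  for (d in seq_len(n)) {
    P <- P %*% A
    powers[[d + 1]] <- P
    newly <- is.infinite(D) & P > 0
    D[newly] <- d
  }
  list(D = D, powers = powers)
}

bf_path_counts <- function(A) {
  bd <- bf_distances(A)
  n <- nrow(A)
  Np <- matrix(0, n, n)
  fin <- is.finite(bd$D) & bd$D > 0
  Np[fin] <- mapply(function(i, j) bd$powers[[bd$D[i, j] + 1]][i, j],
                    row(A)[fin], col(A)[fin])
  list(D = bd$D, Np = Np, powers = bd$powers)
}

bf_path_length <- function(A) {
  D <- bf_distances(A)$D
  vapply(seq_len(nrow(A)), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) NA_real_ else mean(d)
  }, numeric(1))
}

bf_clustering <- function(A) {
  vapply(seq_len(nrow(A)), function(i) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(A[nb, nb]) / 2
    e / (k * (k - 1) / 2)
  }, numeric(1))
}

bf_betweenness <- function(A) {
  pc <- bf_path_counts(A)
  n <- nrow(A)
  bc <- numeric(n)
  for (i in seq_len(n))
    for (j in seq_len(n - 1))
      for (m in (j + 1):n) {
        if (j == i || m == i) next
        if (!is.finite(pc$D[j, m])) next
        a <- pc$D[j, i]
        b <- pc$D[i, m]
        if (!is.finite(a) || !is.finite(b) || a + b != pc$D[j, m]) next
        through <- pc$powers[[a + 1]][j, i] * pc$powers[[b + 1]][i, m]
        bc[i] <- bc[i] + through / pc$Np[j, m]
      }
  bc
}

# Erdos-Renyi-style random symmetric 0/1 matrix
rand_graph <- function(n, p = 0.4) {
  A <- matrix(0L, n, n)
  up <- upper.tri(A)
  A[up] <- as.integer(runif(sum(up)) < p)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

# ring lattice on n nodes, each connected to k nearest neighbours
ring_lattice <- function(n, k = 4) {
  A <- matrix(0L, n, n)
  for (i in seq_len(n))
    for (s in seq_len(k / 2)) {
      j <- ((i - 1 + s) %% n) + 1
      A[i, j] <- A[j, i] <- 1L
    }
  A
}

adjacency_from_edges <- function(n, edges) {
  A <- matrix(0L, n, n)
  for (e in edges) {
    A[e[1], e[2]] <- 1L
    A[e[2], e[1]] <- 1L
  }
  A
}
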