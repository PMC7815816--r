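as_adjacency <- function(adj) {
  A <- unclass(adj)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  storage.mode(A) <- "integer"
  if (any(A != 0L & A != 1L)) stop("adjacency must be binary")
  if (any(A != t(A))) stop("adjacency must be symmetric")
  diag(A) <- 0L
  A
}

#' Nodal degree
#'
#' Number of connections of each node: the row sums of the binary
#' adjacency matrix.
#'
#' @param adj binary symmetric adjacency matrix.
#' @return Integer vector of degrees.
#' @export
degree <- function(adj) {
  A <- as_adjacency(adj)
  as.integer(rowSums(A))
}

#' Nodal clustering coefficient
#'
#' For node i with neighbourhood subgraph g_i: the number of edges among
#' the neighbours divided by the number possible, k_i(k_i - 1)/2. Nodes
#' with fewer than two neighbours (undefined denominator) get 0.
#'
#' @param adj binary symmetric adjacency matrix.
#' @return Numeric vector in \[0, 1\].
#' @export
clustering_coef <- function(adj) {
  as.numeric(cpp_clustering(as_adjacency(adj)))
}

#' Nodal characteristic path length
#'
#' L_i is the mean over the other nodes of the minimum number of edges
#' (BFS shortest-path length) from node i. By default unreachable pairs
#' are excluded from the mean, so L stays finite on fragmented graphs;
#' isolated nodes get `NA`. `mode = "largest"` instead restricts the
#' computation to the largest connected component (all other nodes `NA`).
#'
#' @param adj binary symmetric adjacency matrix.
#' @param mode `"all"` (default: per-node mean over reachable partners) or
#'   `"largest"` (largest connected component only).
#' @return Numeric vector (NA where undefined).
#' @export
path_length <- function(adj, mode = c("all", "largest")) {
  mode <- match.arg(mode)
  A <- as_adjacency(adj)
  if (mode == "largest" && nrow(A) > 0) {
    comp <- graph_components(A)
    keep <- comp == which.max(tabulate(comp))
    L <- rep(NA_real_, nrow(A))
    if (sum(keep) >= 2)
      L[keep] <- as.numeric(cpp_path_length(A[keep, keep, drop = FALSE]))
    return(L)
  }
  as.numeric(cpp_path_length(A))
}

# connected components of a graph (label vector), via BFS in C++
graph_components <- function(A) {
  n <- nrow(A)
  lab <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    q <- s
    lab[s] <- cur
    while (length(q)) {
      v <- q[1]
      q <- q[-1]
      nb <- which(A[v, ] != 0L & lab == 0L)
      lab[nb] <- cur
      q <- c(q, nb)
    }
  }
  lab
}

#' Nodal betweenness centrality
#'
#' BC_i sums, over all unordered pairs (j, m) with i distinct from both,
#' the proportion of shortest j-m paths passing through i. Computed with
#' Brandes' accumulation, which equals exhaustive shortest-path
#' enumeration; no normalization, no endpoint inclusion.
#'
#' @param adj binary symmetric adjacency matrix.
#' @return Numeric vector (>= 0).
#' @export
betweenness <- function(adj) {
  as.numeric(cpp_betweenness(as_adjacency(adj)))
}

#' All nodal metrics of one network
#'
#' @param adj binary symmetric adjacency matrix.
#' @param include_betweenness compute betweenness centrality too (the most
#'   expensive metric)? Default `TRUE`.
#' @param path_mode passed to [path_length()].
#' @return `data.frame` with columns `node_id`, `k`, `c`, `L` and (when
#'   requested) `BC`.
#' @export
node_metrics <- function(adj, include_betweenness = TRUE,
                         path_mode = c("all", "largest")) {
  A <- as_adjacency(adj)
  out <- data.frame(node_id = seq_len(nrow(A)),
                    k = degree(A),
                    c = clustering_coef(A),
                    L = path_length(A, mode = path_mode))
  if (include_betweenness) out$BC <- betweenness(A)
  out
}

#' Network-level means of nodal metrics
#'
#' C_network is the mean clustering coefficient over all N nodes;
#' L_network the mean characteristic path length over the nodes where L is
#' defined.
#'
#' @param nm `data.frame` from [node_metrics()], or an adjacency matrix.
#' @return List with `C_network` and `L_network`.
#' @export
global_means <- function(nm) {
  if (is.matrix(nm)) nm <- node_metrics(nm, include_betweenness = FALSE)
  if (nrow(nm) < 1) stop("need at least one node")
  list(C_network = mean(nm$c), L_network = mean(nm$L, na.rm = TRUE))
}

#' Degree-preserving randomized reference graphs
#'
#' Produces `mu` randomized versions of a graph with identical size and
#' degree sequence, by Maslov-Sneppen double-edge swaps: repeatedly pick
#' two edges (a,b) and (c,d) and rewire them to (a,d) and (c,b) unless that
#' would create a self-loop or duplicate edge. Each reference accumulates
#' `swaps_per_edge` accepted swaps per edge, with an attempt cap of 100x
#' the target so rigid graphs (e.g. complete graphs, where every swap is
#' rejected) terminate; if no swap could be accepted a warning is raised
#' and the reference is a copy of the input.
#'
#' @param adj binary symmetric adjacency matrix with >= 2 edges.
#' @param mu number of references (default 5).
#' @param swaps_per_edge accepted swaps per edge (default 10).
#' @param seed RNG seed (restored on exit).
#' @return List of `mu` adjacency matrices.
#' @export
random_reference <- function(adj, mu = 5L, swaps_per_edge = 10L, seed = 1L) {
  A <- as_adjacency(adj)
  m <- sum(A) / 2
  if (m < 2) stop("graph must have at least 2 edges")
  if (mu < 1) stop("`mu` must be >= 1")
  target <- swaps_per_edge * m
  with_seed(seed, {
    refs <- vector("list", mu)
    for (r in seq_len(mu)) {
      B <- cpp_double_edge_swap(A, target, 100 * target)
      if (attr(B, "accepted_swaps") == 0)
        warning("no swappable edge pairs; reference equals the input graph")
      attr(B, "accepted_swaps") <- NULL
      refs[[r]] <- structure(B, class = c("adjacency_matrix", "matrix"))
    }
    refs
  })
}

#' Small-world coefficients of a binary network
#'
#' Normalizes the network's mean clustering C_network and mean path length
#' L_network against the averages over `mu` degree-preserving randomized
#' references: gamma = C_network / C_random_mean, lambda = L_network /
#' L_random_mean, and the small-world coefficient sigma = gamma / lambda.
#' A small-world network has gamma > 1, lambda ~ 1 and sigma > 1.
#'
#' @param adj binary symmetric adjacency matrix.
#' @param mu number of randomized references (default 5).
#' @param swaps_per_edge accepted double-edge swaps per edge per reference.
#' @param seed RNG seed for the randomization.
#' @param path_mode passed to [path_length()].
#' @return Object of class `global_metrics`: list with `C_network`,
#'   `L_network`, `C_random_mean`, `L_random_mean`, `gamma`, `lambda`,
#'   `sigma`, `mu`.
#' @export
small_world <- function(adj, mu = 5L, swaps_per_edge = 10L, seed = 1L,
                        path_mode = c("all", "largest")) {
  path_mode <- match.arg(path_mode)
  A <- as_adjacency(adj)
  g <- global_means(node_metrics(A, include_betweenness = FALSE,
                                 path_mode = path_mode))
  if (!is.finite(g$L_network))
    stop("no node has a defined path length; graph has no edges?")
  refs <- random_reference(A, mu = mu, swaps_per_edge = swaps_per_edge,
                           seed = seed)
  gr <- lapply(refs, function(B)
    global_means(node_metrics(B, include_betweenness = FALSE,
                              path_mode = path_mode)))
  C_rand <- mean(vapply(gr, `[[`, numeric(1), "C_network"))
  L_rand <- mean(vapply(gr, `[[`, numeric(1), "L_network"))
  structure(list(C_network = g$C_network, L_network = g$L_network,
                 C_random_mean = C_rand, L_random_mean = L_rand,
                 gamma = g$C_network / C_rand,
                 lambda = g$L_network / L_rand,
                 sigma = (g$C_network / C_rand) / (g$L_network / L_rand),
                 mu = mu),
            class = "global_metrics")
}

#' @export
print.global_metrics <- function(x, digits = 4, ...) {
  cat("Global network metrics (mu =", x$mu, "randomized references)\n")
  v <- unlist(x[c("C_network", "L_network", "C_random_mean",
                  "L_random_mean", "gamma", "lambda", "sigma")])
  print(round(v, digits))
  invisible(x)
}
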