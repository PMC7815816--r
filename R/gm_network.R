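#' Fit a single-subject gray-matter structural network
#'
#' The central estimator: from one gray-matter density volume and an
#' analysis mask it (1) tiles the mask into 3x3x3-voxel cube nodes, (2)
#' scores every node pair with the orientation-maximized Pearson
#' correlation, (3) builds an empirical null by correlating randomly
#' permuted cube pairs, (4) finds the similarity threshold controlling the
#' false discovery rate of edges at `q`, (5) binarizes, and (6) computes
#' nodal metrics (degree, clustering, path length, betweenness) and global
#' small-world coefficients against `mu` degree-preserving randomized
#' reference graphs.
#'
#' All randomness (null sampling, graph randomization) derives
#' deterministically from `seed`; refitting with the same inputs and seed
#' reproduces the network exactly.
#'
#' @param volume gray-matter density volume ([density_volume()], 3D array,
#'   or a NIfTI file path).
#' @param mask binary analysis mask on the same grid (same types accepted);
#'   `NULL` uses every voxel.
#' @param q edge false-discovery-rate level (default 0.05).
#' @param mu number of randomized reference graphs (default 5).
#' @param n_null empirical-null sample size (default 10000).
#' @param swaps_per_edge accepted double-edge swaps per edge per reference.
#' @param min_inside_fraction minimum in-mask fraction for a cube node.
#' @param orientation_set `"orthogonal"` (48 exact cube symmetries,
#'   default) or `"rot45"` (adds nearest-neighbour 45-degree rotations).
#' @param seed master seed for this fit.
#' @param include_betweenness compute nodal betweenness (the slowest
#'   metric)? Default `TRUE`.
#' @param path_mode `"all"` (mean over reachable partners, default) or
#'   `"largest"` (largest connected component).
#' @return Object of class `gm_network`: list with elements `nodes`
#'   (`cube_nodes`), `similarity`, `null`, `threshold`, `adjacency`,
#'   `node_metrics` (data.frame), `global` (`global_metrics`), and the
#'   call parameters.
#' @seealso [parcellate_cubes()], [similarity_matrix()],
#'   [fdr_edge_threshold()], [small_world()], [metric_maps()]
#' @export
#' @examples
#' cfg <- simulation_config(grid_shape = c(12, 12, 12), n_per_group = 3)
#' sub <- generate_subject(cfg, "control", subject_seed = 7)
#' net <- gm_network(sub$volume, n_null = 1000, seed = 1)
#' net
gm_network <- function(volume, mask = NULL, q = 0.05, mu = 5L,
                       n_null = 10000L, swaps_per_edge = 10L,
                       min_inside_fraction = 1,
                       orientation_set = c("orthogonal", "rot45"),
                       seed = 1L, include_betweenness = TRUE,
                       path_mode = c("all", "largest")) {
  orientation_set <- match.arg(orientation_set)
  path_mode <- match.arg(path_mode)
  if (is.character(volume)) volume <- read_volume(volume)
  if (is.character(mask)) mask <- read_volume(mask)
  volume <- as_density_volume(volume)

  maps <- cube_orientations(orientation_set)
  nodes <- parcellate_cubes(volume, mask,
                            min_inside_fraction = min_inside_fraction)
  sim <- similarity_matrix(nodes, orientations = maps)
  null <- empirical_null(nodes, n_samples = n_null,
                         seed = child_seed(seed, 1L), orientations = maps)
  thr <- fdr_edge_threshold(sim, null, q = q)
  adj <- binarize(sim, thr)
  nm <- node_metrics(adj, include_betweenness = include_betweenness,
                     path_mode = path_mode)
  glob <- if (sum(adj) / 2 >= 2) {
    small_world(adj, mu = mu, swaps_per_edge = swaps_per_edge,
                seed = child_seed(seed, 2L), path_mode = path_mode)
  } else NULL

  structure(list(nodes = nodes, similarity = sim, null = null,
                 threshold = as.numeric(thr),
                 n_significant = attr(thr, "n_significant"),
                 adjacency = adj, node_metrics = nm, global = glob,
                 q = q, mu = mu, seed = seed,
                 orientation_set = orientation_set,
                 path_mode = path_mode),
            class = "gm_network")
}

#' @export
print.gm_network <- function(x, ...) {
  n <- nrow(x$adjacency)
  m <- sum(x$adjacency) / 2
  cat("Single-subject gray-matter network\n")
  cat("  nodes:", n, "(", sum(x$nodes$degenerate), "degenerate )\n")
  cat("  edges:", m, sprintf("(density %.3f)", m / (n * (n - 1) / 2)), "\n")
  cat("  FDR q:", x$q, " threshold:", signif(x$threshold, 4), "\n")
  if (!is.null(x$global))
    cat(sprintf("  gamma %.3f  lambda %.3f  sigma %.3f  (mu = %d)\n",
                x$global$gamma, x$global$lambda, x$global$sigma, x$global$mu))
  invisible(x)
}

#' @export
summary.gm_network <- function(object, ...) {
  nm <- object$node_metrics
  out <- list(
    n_nodes = nrow(nm),
    n_edges = sum(object$adjacency) / 2,
    threshold = object$threshold,
    q = object$q,
    node_summary = do.call(rbind, lapply(
      intersect(c("k", "c", "L", "BC"), names(nm)),
      function(v) {
        x <- nm[[v]]
        data.frame(metric = v, mean = mean(x, na.rm = TRUE),
                   sd = sd(x, na.rm = TRUE),
                   min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE))
      })),
    global = object$global)
  class(out) <- "summary.gm_network"
  out
}

#' @export
print.summary.gm_network <- function(x, ...) {
  cat("gm_network:", x$n_nodes, "nodes,", x$n_edges, "edges",
      "(FDR q =", x$q, ", threshold =", signif(x$threshold, 4), ")\n\n")
  cat("Nodal metrics:\n")
  print(x$node_summary, row.names = FALSE, digits = 4)
  if (!is.null(x$global)) {
    cat("\n")
    print(x$global)
  }
  invisible(x)
}

#' Plot a fitted gray-matter network
#'
#' Two panels: the binary adjacency matrix (nodes in raster order) and the
#' degree distribution.
#'
#' @param x a `gm_network`.
#' @param ... ignored.
#' @export
plot.gm_network <- function(x, ...) {
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  A <- unclass(x$adjacency)
  image(seq_len(nrow(A)), seq_len(ncol(A)), A, col = gray.colors(2, 1, 0),
        xlab = "node", ylab = "node", main = "adjacency", useRaster = TRUE)
  hist(x$node_metrics$k, breaks = "FD", xlab = "degree k",
       main = "degree distribution", col = "gray70", border = "white")
  invisible(x)
}
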