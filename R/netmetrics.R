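#' Average connectivity <k> = L / N
#'
#' Total number of directed effective connections divided by the number of
#' neurons; each directed edge is counted once.
#'
#' @param A binary directed adjacency matrix, zero diagonal.
#' @return scalar <k>.
#' @export
average_connectivity <- function(A) {
  stop_if_not_square(A)
  if (nrow(A) == 0) stop("empty network", call. = FALSE)
  sum(A) / nrow(A)
}

#' Shortest topological path lengths
#'
#' Directed unweighted shortest hop counts `d[i, j]`; unreachable pairs get
#' `Inf` and the diagonal is 0.
#'
#' @param A binary directed adjacency matrix.
#' @return numeric matrix of path lengths.
#' @export
shortest_topological_paths <- function(A) {
  stop_if_not_square(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  d <- igraph::distances(g, mode = "out", algorithm = "unweighted")
  dimnames(d) <- NULL
  d
}

#' Global efficiency
#'
#' `GE = 1 / (N (N - 1)) * sum_{i != j} 1 / d_ij`, the mean inverse shortest
#' topological path length over ordered pairs, with `1 / Inf = 0` for
#' non-connected pairs. GE is 1 for a fully connected network and 0 for a
#' totally disconnected one.
#'
#' @param x either a path-length matrix from
#'   [shortest_topological_paths()] or a binary adjacency matrix (detected by
#'   content: adjacency contains only 0/1).
#' @return GE in \[0, 1\].
#' @export
global_efficiency <- function(x) {
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  N <- nrow(x)
  if (N < 2) stop("global efficiency needs at least 2 nodes", call. = FALSE)
  d <- if (all(x[is.finite(x)] %in% c(0, 1))) shortest_topological_paths(x) else x
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (N * (N - 1))
}

#' Modularity statistic Q of a partition
#'
#' Exact evaluation of
#' `Q = 1/(2m) * sum_ij (A_ij - k_i k_j / (2m)) delta(c_i, c_j)` with
#' `k_i = sum_j A_ij` (row sums) and `m = (1/2) sum_ij A_ij`, applied to the
#' binarized directed matrix as given. Q is 0 when the entire network forms
#' a single community. Set `symmetrize = TRUE` to evaluate on the undirected
#' version `(A + t(A) > 0)` instead (the convention of some connectivity
#' toolboxes).
#'
#' @param A binary directed adjacency matrix.
#' @param communities integer community label per node (covers all nodes).
#' @param symmetrize evaluate on the symmetrized matrix (default FALSE).
#' @return scalar Q.
#' @export
modularity_q <- function(A, communities, symmetrize = FALSE) {
  stop_if_not_square(A)
  n <- nrow(A)
  if (length(communities) != n || anyNA(communities)) {
    stop("communities must label every node", call. = FALSE)
  }
  if (symmetrize) A <- (A + t(A) > 0) * 1
  m <- sum(A) / 2
  if (m == 0) stop("modularity is undefined for a network with no edges",
                   call. = FALSE)
  k <- rowSums(A)
  q <- 0
  for (cc in unique(communities)) {
    idx <- communities == cc
    q <- q + sum(A[idx, idx]) - sum(k[idx])^2 / (2 * m)
  }
  q / (2 * m)
}

#' Louvain community detection
#'
#' Runs the Louvain algorithm on the symmetrized (undirected, weight =
#' number of directions present) graph, with node order randomized by
#' `seed` for deterministic tie-breaking, and reports the modularity of the
#' found partition evaluated by [modularity_q()] on the matrix as given.
#' The partition never scores below the trivial single-community partition
#' (Q = 0): if it would, the single community is returned instead.
#'
#' @param A binary directed adjacency matrix with at least one edge.
#' @param seed integer RNG seed (fixed default for reproducibility).
#' @param symmetrize_q evaluate the reported Q on the symmetrized matrix.
#' @return list with `communities` (integer labels) and `Q`.
#' @export
louvain_communities <- function(A, seed = 1, symmetrize_q = FALSE) {
  stop_if_not_square(A)
  if (sum(A) == 0) stop("community detection needs at least one edge",
                        call. = FALSE)
  W <- A + t(A)
  memb <- with_seed(seed, {
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    as.integer(igraph::membership(igraph::cluster_louvain(g)))
  })
  q <- modularity_q(A, memb, symmetrize = symmetrize_q)
  if (q < 0) {
    memb <- rep(1L, nrow(A))
    q <- modularity_q(A, memb, symmetrize = symmetrize_q)
  }
  list(communities = memb, Q = q)
}

#' Summary network traits of a binarized connectivity matrix
#'
#' Computes the trait set used to compare functional networks: neuron count
#' N, total effective connections L, average connectivity <k> = L/N, global
#' efficiency, Louvain modularity Q with its community partition, and the
#' shortest-path matrix.
#'
#' @param A binary directed adjacency matrix.
#' @param seed seed for the Louvain tie-breaking.
#' @param symmetrize_q passed to [louvain_communities()].
#' @return object of class `network_traits`.
#' @export
network_traits <- function(A, seed = 1, symmetrize_q = FALSE) {
  stop_if_not_square(A)
  n <- nrow(A)
  L <- sum(A)
  d <- shortest_topological_paths(A)
  ge <- if (n >= 2) global_efficiency(d) else NA_real_
  if (L > 0) {
    lv <- louvain_communities(A, seed = seed, symmetrize_q = symmetrize_q)
    Q <- lv$Q
    communities <- lv$communities
  } else {
    Q <- NA_real_
    communities <- rep(1L, n)
  }
  structure(list(n = n, L = L, mean_k = L / n, GE = ge, Q = Q,
                 communities = communities, d = d),
            class = "network_traits")
}

#' @export
print.network_traits <- function(x, ...) {
  cat(sprintf("<network_traits> N=%d L=%d <k>=%.2f GE=%.3f Q=%s (%d communities)\n",
              x$n, x$L, x$mean_k, x$GE,
              if (is.na(x$Q)) "NA" else sprintf("%.3f", x$Q),
              length(unique(x$communities))))
  invisible(x)
}

#' Traits report JSON writer
#'
#' @param traits a [network_traits()] object.
#' @param path JSON path.
#' @export
write_traits <- function(traits, path) {
  jsonlite::write_json(
    list(N = traits$n, L = traits$L, mean_k = traits$mean_k, GE = traits$GE,
         Q = traits$Q, communities = traits$communities),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
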