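#' Generate a ground-truth neuronal network
#'
#' Builds a directed random network embedded in a cylindrical culture volume,
#' used as simulation truth for validating spike inference and effective
#' connectivity. Edge probability decays with somatic distance and is boosted
#' within communities, then rescaled so the realized edge density matches the
#' request. Communities are spatially coherent (angular sectors of the
#' cylinder), mirroring the observation that functionally grouped neurons tend
#' to be physically nearby. 80% of neurons are marked excitatory.
#'
#' @param n_neurons number of neurons (>= 2).
#' @param density target edge density over ordered pairs, in (0, 1].
#' @param n_communities number of planted communities (>= 1).
#' @param spatial_decay length scale (um) of the edge-probability decay.
#' @param seed integer RNG seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param radius_um,height_um cylinder geometry (um) holding the somata.
#' @param p_excitatory fraction of excitatory neurons (default 0.8).
#' @param community_boost multiplicative within-community edge-probability
#'   boost (> 1 makes within-community edges more likely than between).
#' @param weight_range optional length-2 range for uniform random edge
#'   weights; the default `NULL` gives every edge unit coupling strength
#'   (the minimal cascade truth).
#' @return an object of class `ground_truth_network`: list with `n_neurons`,
#'   `positions` (n x 3 matrix, um), `adjacency` (n x n binary, no
#'   self-edges), `weights` (nonnegative coupling strengths, 0 off edges),
#'   `community_labels`, `excitatory_mask`, and `params`.
#' @export
generate_network <- function(n_neurons, density = 0.1, n_communities = 1,
                             spatial_decay = 400, seed = 1,
                             radius_um = 3000, height_um = 600,
                             p_excitatory = 0.8, community_boost = 4,
                             weight_range = NULL) {
  if (n_neurons < 2) stop("n_neurons must be at least 2", call. = FALSE)
  stopifnot(density > 0, density <= 1, n_communities >= 1,
            spatial_decay > 0, community_boost >= 1)
  n <- as.integer(n_neurons)
  with_seed(seed, {
    r <- radius_um * sqrt(stats::runif(n))
    th <- stats::runif(n, 0, 2 * pi)
    positions <- cbind(x = r * cos(th), y = r * sin(th),
                       z = stats::runif(n, -height_um / 2, height_um / 2))
    # spatially coherent, guaranteed non-empty communities: angular sectors
    labels <- if (n_communities > 1) {
      as.integer(cut(rank(th, ties.method = "first"),
                     breaks = n_communities, labels = FALSE))
    } else rep(1L, n)

    d <- as.matrix(stats::dist(positions))
    w <- exp(-d / spatial_decay)
    same <- outer(labels, labels, `==`)
    w[same] <- w[same] * community_boost
    diag(w) <- 0
    off <- row(w) != col(w)

    if (density >= 1) {
      p <- matrix(1, n, n)
    } else {
      f <- function(s) mean(pmin(s * w[off], 1)) - density
      hi <- 1
      while (f(hi) < 0 && hi < 1e12) hi <- hi * 10
      s <- stats::uniroot(f, c(0, hi), tol = 1e-12)$root
      p <- pmin(s * w, 1)
    }
    diag(p) <- 0
    adjacency <- matrix(stats::rbinom(n * n, 1, as.vector(p)), n, n)
    diag(adjacency) <- 0L

    weights <- if (is.null(weight_range)) {
      adjacency * 1.0
    } else {
      matrix(stats::runif(n * n, weight_range[1], weight_range[2]), n, n) * adjacency
    }
    n_exc <- round(p_excitatory * n)
    excitatory <- rep(FALSE, n)
    excitatory[sample.int(n, n_exc)] <- TRUE

    structure(
      list(n_neurons = n, positions = positions, adjacency = adjacency,
           weights = weights, community_labels = labels,
           excitatory_mask = excitatory,
           params = list(density = density, n_communities = n_communities,
                         spatial_decay = spatial_decay, seed = seed,
                         radius_um = radius_um, height_um = height_um,
                         p_excitatory = p_excitatory,
                         community_boost = community_boost)),
      class = "ground_truth_network")
  })
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf(
    "<ground_truth_network> %d neurons, %d directed edges (density %.3f), %d communities\n",
    x$n_neurons, sum(x$adjacency),
    sum(x$adjacency) / (x$n_neurons * (x$n_neurons - 1)),
    length(unique(x$community_labels))))
  invisible(x)
}

#' Write / read ground truth as JSON
#'
#' The adjacency is stored as an edge list together with positions, labels and
#' all generator parameters (including the seed), so a data file can always be
#' traced back to its truth.
#'
#' @param net a `ground_truth_network`.
#' @param path output JSON file.
#' @return `path` (write) or a `ground_truth_network` (read).
#' @export
write_ground_truth <- function(net, path) {
  edges <- which(net$adjacency == 1, arr.ind = TRUE)
  jsonlite::write_json(
    list(n_neurons = net$n_neurons,
         edges = data.frame(from = edges[, 1], to = edges[, 2],
                            weight = net$weights[edges]),
         positions = as.data.frame(net$positions),
         community_labels = net$community_labels,
         excitatory_mask = net$excitatory_mask,
         params = net$params),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- g$n_neurons
  A <- matrix(0L, n, n)
  W <- matrix(0, n, n)
  if (length(g$edges)) {
    idx <- cbind(g$edges$from, g$edges$to)
    A[idx] <- 1L
    W[idx] <- g$edges$weight
  }
  structure(
    list(n_neurons = n, positions = as.matrix(g$positions), adjacency = A,
         weights = W, community_labels = g$community_labels,
         excitatory_mask = g$excitatory_mask, params = g$params),
    class = "ground_truth_network")
}
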