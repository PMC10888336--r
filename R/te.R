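#' Transfer-entropy configuration
#'
#' @param bin_s raster binning (s). Default two frame periods at 33 fps.
#' @param markov_order history length k (bins) for both source and target.
#' @param z_threshold significance threshold on the normalized TE (default
#'   2; an effective connection I -> J is declared when z > 2, strictly).
#' @param delay_bins source-target delay (bins, >= 1): the most recent source
#'   bin used to predict the target's next state lags it by `delay_bins`.
#'   The same-bin (instantaneous) term is always excluded.
#' @param null how the normalization null is formed: `"pooled"` uses the
#'   mean/sd of the pooled TE estimates over all ordered pairs of the same
#'   recording; `"surrogate"` uses per-pair circular time-shift surrogates.
#' @param conditioning `"none"`, or `"exclude_bursts"` to drop time bins in
#'   which more than `burst_fraction` of neurons are simultaneously active
#'   (the generalized conditioning that avoids network bursts dominating the
#'   estimate).
#' @param burst_fraction population-fraction threshold for burst exclusion.
#' @param n_surrogate number of surrogates per pair in `"surrogate"` mode.
#' @param seed RNG seed for surrogate shifts.
#' @return list of class `te_config`.
#' @export
te_config <- function(bin_s = 2 / 33, markov_order = 2, z_threshold = 2,
                      delay_bins = 1, null = c("pooled", "surrogate"),
                      conditioning = c("none", "exclude_bursts"),
                      burst_fraction = 0.4, n_surrogate = 20, seed = 1) {
  null <- match.arg(null)
  conditioning <- match.arg(conditioning)
  stopifnot(bin_s > 0, markov_order >= 1, z_threshold > 0, delay_bins >= 1,
            burst_fraction > 0, burst_fraction <= 1, n_surrogate >= 5)
  structure(list(bin_s = bin_s, markov_order = as.integer(markov_order),
                 z_threshold = z_threshold, delay_bins = as.integer(delay_bins),
                 null = null, conditioning = conditioning,
                 burst_fraction = burst_fraction,
                 n_surrogate = as.integer(n_surrogate), seed = seed),
            class = "te_config")
}

#' Binarize a spike raster into a neuron x bin matrix
#'
#' A bin is 1 when the neuron has at least one event in it (saturating).
#'
#' @param raster a [spike_raster()].
#' @param bin_s bin width (s).
#' @return binary integer matrix `[neuron, bin]` with
#'   `ceiling(duration / bin_s)` columns.
#' @export
binarize_raster <- function(raster, bin_s) {
  stopifnot(inherits(raster, "spike_raster"), bin_s > 0)
  nb <- as.integer(ceiling(raster$duration / bin_s - 1e-9))
  M <- matrix(0L, raster$n_neurons, nb)
  for (i in seq_len(raster$n_neurons)) {
    t <- raster$events[[i]]
    if (length(t)) {
      b <- pmin(nb, as.integer(floor(t / bin_s)) + 1L)
      M[i, b] <- 1L
    }
  }
  M
}

# History codes: h[t] = sum_{a=0..k-1} v[t-a] * 2^a, defined for t >= k.
history_codes <- function(v, k) {
  n <- length(v)
  h <- rep.int(NA_integer_, n)
  acc <- integer(n - k + 1)
  for (a in 0:(k - 1)) acc <- acc + v[(k - a):(n - a)] * 2L^a
  h[k:n] <- acc
  h
}

# TE (bits) from a joint count array over (y_next, y_hist, x_hist).
te_from_counts <- function(counts, K) {
  arr <- array(counts, c(2L, K, K))
  N <- sum(arr)
  if (N == 0) return(0)
  m_hx <- colSums(arr)                  # (y_hist, x_hist)
  m_yh <- apply(arr, c(1, 2), sum)      # (y_next, y_hist)
  m_h <- colSums(m_yh)                  # (y_hist)
  a_mh <- array(rep(m_h, each = 2L), c(2L, K, K))
  a_mhx <- array(rep(as.vector(m_hx), each = 2L), c(2L, K, K))
  a_myh <- array(rep(as.vector(m_yh), times = K), c(2L, K, K))
  pos <- arr > 0
  sum(arr[pos] * log2((arr[pos] * a_mh[pos]) / (a_mhx[pos] * a_myh[pos]))) / N
}

#' Binned transfer entropy between two binary series
#'
#' Plug-in (maximum-likelihood histogram) estimate of
#' `TE(X -> Y) = sum p(y_{t+1}, y_t^{(k)}, x^{(k)}) log2 [ p(y_{t+1} | y_t^{(k)}, x^{(k)}) / p(y_{t+1} | y_t^{(k)}) ]`,
#' in bits, where `y_t^{(k)}` is the target's k-bin history and `x^{(k)}`
#' the source's k-bin history ending `delay_bins` before the predicted bin.
#' The estimate is nonnegative and exactly 0 for a constant source. No bias
#' correction is applied: with binary alphabets and long recordings the bias
#' is small and common across pairs, and the pooled z-normalization of
#' [te_matrix()] absorbs it.
#'
#' @param x,y binary vectors of equal length (source, target).
#' @param cfg a [te_config()].
#' @return TE in bits.
#' @export
transfer_entropy <- function(x, y, cfg = te_config()) {
  if (length(x) != length(y)) {
    stop("source and target series must have equal length", call. = FALSE)
  }
  k <- cfg$markov_order
  d <- cfg$delay_bins
  n <- length(x)
  if (n < k + d + 1) stop("series too short for the requested history", call. = FALSE)
  if (all(x == x[1])) return(0)
  hx <- history_codes(as.integer(x), k)
  hy <- history_codes(as.integer(y), k)
  ts <- (k + d - 1):(n - 1)
  K <- 2L^k
  idx <- 1L + as.integer(y[ts + 1]) + 2L * hy[ts] + (2L * K) * hx[ts - d + 1L]
  te_from_counts(tabulate(idx, 2L * K * K), K)
}

#' Effective connectivity from a binarized raster
#'
#' Computes TE for every ordered neuron pair, normalizes each estimate
#' against the null distribution (`z = (TE - <TE_joint>) / sigma_joint`,
#' where by default `<TE_joint>` and `sigma_joint` are the mean and sd of the
#' pooled pair estimates of the same recording, the diagonal excluded), and
#' binarizes: `A[i, j] = 1` iff `z[i, j] > z_threshold` (strict). Ties at
#' exactly the threshold are not significant.
#'
#' @param bins binary matrix `[neuron, bin]` from [binarize_raster()].
#' @param cfg a [te_config()].
#' @return object of class `effective_connectivity`: `te`, `z`, `A`
#'   (diagonals NA/0), `null_mean`, `null_sd`, `config`.
#' @export
te_matrix <- function(bins, cfg = te_config()) {
  stopifnot(is.matrix(bins), nrow(bins) >= 2)
  n <- nrow(bins)
  nb <- ncol(bins)
  k <- cfg$markov_order
  d <- cfg$delay_bins
  if (nb < k + d + 1) stop("too few bins for the requested history", call. = FALSE)
  K <- 2L^k
  ts <- (k + d - 1):(nb - 1)

  if (cfg$conditioning == "exclude_bursts") {
    frac <- colMeans(bins)
    valid_bin <- frac <= cfg$burst_fraction
    # a prediction sample at t is kept if every bin it touches is valid
    keep <- rep(TRUE, length(ts))
    for (off in c(1L, 0:(-(k - 1)), (1L - d):(1L - d - k + 1L))) {
      keep <- keep & valid_bin[ts + off]
    }
  } else {
    keep <- rep(TRUE, length(ts))
  }
  ts <- ts[keep]
  if (length(ts) < 10) stop("no usable time bins after conditioning", call. = FALSE)

  hx <- matrix(NA_integer_, n, nb)
  yterm <- matrix(NA_integer_, n, length(ts))
  xterm <- matrix(NA_integer_, n, length(ts))
  const_src <- logical(n)
  for (i in seq_len(n)) {
    h <- history_codes(bins[i, ], k)
    yterm[i, ] <- as.integer(bins[i, ts + 1]) + 2L * h[ts]
    xterm[i, ] <- h[ts - d + 1L]
    const_src[i] <- all(bins[i, ] == bins[i, 1])
  }

  te <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    xi <- (2L * K) * xterm[i, ]
    for (j in seq_len(n)) {
      if (i == j) next
      te[i, j] <- if (const_src[i]) 0 else {
        te_from_counts(tabulate(1L + yterm[j, ] + xi, 2L * K * K), K)
      }
    }
  }

  off <- !is.na(te)
  z <- matrix(NA_real_, n, n)
  if (cfg$null == "pooled") {
    null_mean <- mean(te[off])
    null_sd <- stats::sd(te[off])
    if (!is.finite(null_sd) || null_sd == 0) {
      warning("degenerate TE pool (sigma_joint = 0); no significant connections")
      A <- matrix(0L, n, n)
      return(structure(list(te = te, z = z, A = A, null_mean = null_mean,
                            null_sd = null_sd, config = cfg),
                       class = "effective_connectivity"))
    }
    z[off] <- (te[off] - null_mean) / null_sd
  } else {
    null_mean <- NA_real_
    null_sd <- NA_real_
    nt <- length(ts)
    shifts <- with_seed(cfg$seed,
      sample(seq(floor(nt * 0.1), floor(nt * 0.9)), cfg$n_surrogate,
             replace = cfg$n_surrogate > floor(nt * 0.8)))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || const_src[i]) next
        te_s <- vapply(shifts, function(s) {
          xs <- (2L * K) * xterm[i, c((s + 1):nt, 1:s)]
          te_from_counts(tabulate(1L + yterm[j, ] + xs, 2L * K * K), K)
        }, numeric(1))
        sds <- stats::sd(te_s)
        if (is.finite(sds) && sds > 0) z[i, j] <- (te[i, j] - mean(te_s)) / sds
      }
    }
  }
  A <- matrix(0L, n, n)
  A[off & !is.na(z) & z > cfg$z_threshold] <- 1L
  diag(A) <- 0L
  structure(list(te = te, z = z, A = A, null_mean = null_mean,
                 null_sd = null_sd, config = cfg),
            class = "effective_connectivity")
}

#' @export
print.effective_connectivity <- function(x, ...) {
  n <- nrow(x$A)
  cat(sprintf("<effective_connectivity> %d neurons, %d significant directed connections (z > %g)\n",
              n, sum(x$A), x$config$z_threshold))
  invisible(x)
}

#' Export an effective-connectivity network for graph tools
#'
#' Writes the binarized directed network with node attributes (position,
#' community, degree) as GraphML or GEXF, the input formats of standard
#' network-visualization tools.
#'
#' @param ec an [te_matrix()] result, or a binary adjacency matrix.
#' @param file output path.
#' @param positions optional n x 2 or n x 3 coordinate matrix.
#' @param communities optional integer community labels.
#' @param format "graphml" or "gexf" (default from the file extension).
#' @return `file`, invisibly.
#' @export
export_network <- function(ec, file, positions = NULL, communities = NULL,
                           format = NULL) {
  A <- if (inherits(ec, "effective_connectivity")) ec$A else ec
  stop_if_not_square(A)
  n <- nrow(A)
  format <- format %||% (if (grepl("\\.gexf$", file)) "gexf" else "graphml")
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::V(g)$degree <- as.numeric(rowSums(A) + colSums(A))
  if (!is.null(communities)) igraph::V(g)$community <- as.numeric(communities)
  if (!is.null(positions)) {
    igraph::V(g)$x <- as.numeric(positions[, 1])
    igraph::V(g)$y <- as.numeric(positions[, 2])
    if (ncol(positions) >= 3) igraph::V(g)$z <- as.numeric(positions[, 3])
  }
  if (format == "graphml") {
    igraph::write_graph(g, file, format = "graphml")
  } else {
    write_gexf(A, file, positions, communities)
  }
  invisible(file)
}

# Minimal GEXF 1.2 writer (directed, node attributes only).
write_gexf <- function(A, file, positions = NULL, communities = NULL) {
  n <- nrow(A)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph defaultedgetype="directed">',
    '    <attributes class="node">',
    '      <attribute id="0" title="community" type="integer"/>',
    '      <attribute id="1" title="degree" type="integer"/>',
    '      <attribute id="2" title="x_um" type="double"/>',
    '      <attribute id="3" title="y_um" type="double"/>',
    '    </attributes>',
    '    <nodes>'), con)
  deg <- rowSums(A) + colSums(A)
  for (i in seq_len(n)) {
    com <- if (is.null(communities)) 0L else communities[i]
    px <- if (is.null(positions)) 0 else positions[i, 1]
    py <- if (is.null(positions)) 0 else positions[i, 2]
    writeLines(sprintf(
      '      <node id="%d" label="n%d"><attvalues><attvalue for="0" value="%d"/><attvalue for="1" value="%d"/><attvalue for="2" value="%g"/><attvalue for="3" value="%g"/></attvalues></node>',
      i, i, com, deg[i], px, py), con)
  }
  writeLines('    </nodes>', con)
  writeLines('    <edges>', con)
  e <- which(A == 1, arr.ind = TRUE)
  if (nrow(e)) {
    writeLines(sprintf('      <edge id="%d" source="%d" target="%d"/>',
                       seq_len(nrow(e)), e[, 1], e[, 2]), con)
  }
  writeLines(c('    </edges>', '  </graph>', '</gexf>'), con)
  invisible(file)
}

#' Read a GraphML network back to an adjacency matrix
#'
#' @param file GraphML path.
#' @return binary adjacency matrix (node order = stored node order).
#' @export
read_network <- function(file) {
  g <- igraph::read_graph(file, format = "graphml")
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

#' Dense adjacency / z-matrix CSV writers
#'
#' @param ec an `effective_connectivity`.
#' @param path CSV path.
#' @export
write_adjacency <- function(ec, path) {
  A <- if (inherits(ec, "effective_connectivity")) ec$A else ec
  df <- as.data.frame(A)
  names(df) <- paste0("n", seq_len(ncol(A)))
  utils::write.csv(cbind(neuron = paste0("n", seq_len(nrow(A))), df),
                   path, row.names = FALSE)
  invisible(path)
}
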