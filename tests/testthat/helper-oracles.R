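# Independent oracles used to validate the package implementations.
# These are deliberately written with naive algorithms (explicit loops,
# string-keyed histograms) so they share no code path with the package.

# All-pairs shortest hop counts by Floyd-Warshall.
fw_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Global efficiency by explicit enumeration of ordered pairs.
ge_oracle <- function(A) {
  d <- fw_distances(A)
  n <- nrow(A)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is.finite(d[i, j])) acc <- acc + 1 / d[i, j]
    }
  }
  acc / (n * (n - 1))
}

# Modularity by the naive O(N^2) double sum.
q_oracle <- function(A, comm) {
  n <- nrow(A)
  m <- sum(A) / 2
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (comm[i] == comm[j]) q <- q + A[i, j] - k[i] * k[j] / (2 * m)
    }
  }
  q / (2 * m)
}

# Transfer entropy by a string-keyed joint histogram and explicit
# conditional probabilities.
te_oracle <- function(x, y, k = 1, d = 1) {
  n <- length(x)
  ts <- (k + d - 1):(n - 1)
  yn <- y[ts + 1]
  yh <- vapply(ts, function(t) paste(y[t:(t - k + 1)], collapse = ""), "")
  xh <- vapply(ts, function(t) paste(x[(t - d + 1):(t - d + 2 - k)], collapse = ""), "")
  N <- length(ts)
  full <- paste(yn, yh, xh)
  cond <- paste(yh, xh)
  marg <- paste(yn, yh)
  tab_full <- table(full)
  tab_cond <- table(cond)
  tab_marg <- table(marg)
  tab_h <- table(yh)
  te <- 0
  for (key in names(tab_full)) {
    parts <- strsplit(key, " ")[[1]]
    c_full <- tab_full[[key]]
    c_cond <- tab_cond[[paste(parts[2], parts[3])]]
    c_marg <- tab_marg[[paste(parts[1], parts[2])]]
    c_h <- tab_h[[parts[2]]]
    p <- c_full / N
    te <- te + p * log2((c_full / c_cond) / (c_marg / c_h))
  }
  te
}

# All set partitions of 1..n as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(labels, mx) {
    if (length(labels) == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (v in seq_len(mx + 1)) rec(c(labels, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# Greedy one-to-one matching of detected event times to true times within
# a tolerance; returns the matched fraction of true events.
match_fraction <- function(true_times, det_times, tol) {
  if (!length(true_times)) return(NA_real_)
  used <- rep(FALSE, length(det_times))
  hit <- 0
  for (t in true_times) {
    dt <- abs(det_times - t)
    dt[used] <- Inf
    j <- which.min(dt)
    if (length(j) && is.finite(dt[j]) && dt[j] <= tol) {
      used[j] <- TRUE
      hit <- hit + 1
    }
  }
  hit / length(true_times)
}

# Random directed binary adjacency with zero diagonal.
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(rbinom(n * n, 1, p), n, n)
  diag(A) <- 0L
  A
}

precision_recall <- function(A, truth) {
  tp <- sum(A == 1 & truth == 1)
  c(precision = if (sum(A) > 0) tp / sum(A) else NA_real_,
    recall = tp / sum(truth))
}
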