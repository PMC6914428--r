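# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately re-derive every quantity with plain loops so they share
# no code path with the package implementation.

# modularity by direct double loop over ordered node pairs
bf_modularity <- function(w, membership, gamma = 1) {
  n <- nrow(w)
  two_m <- sum(w)
  k <- rowSums(w)
  q <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j])
        q <- q + w[i, j] - gamma * k[i] * k[j] / two_m
    }
  }
  q / two_m
}

# all set partitions of n elements as membership vectors
# (restricted growth strings); n = 8 gives the 4140 Bell(8) partitions
bf_all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1))
      grow(c(prefix, lab), max(maxlab, lab))
  }
  grow(integer(0), 0L)
  out
}

# exhaustive-search maximum modularity
bf_best_q <- function(w, gamma = 1, partitions = NULL) {
  if (is.null(partitions)) partitions <- bf_all_partitions(nrow(w))
  best <- -Inf
  for (p in partitions) {
    q <- bf_modularity(w, p, gamma)
    if (q > best) best <- q
  }
  best
}

# per-node participation coefficient by explicit loops
bf_participation <- function(w, labels) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- 0
    for (j in seq_len(n)) k <- k + w[i, j]
    if (k == 0) { out[i] <- 0; next }
    acc <- 0
    for (s in unique(labels)) {
      kis <- 0
      for (j in which(labels == s)) kis <- kis + w[i, j]
      acc <- acc + (kis / k)^2
    }
    out[i] <- 1 - acc
  }
  out
}

# within-hemisphere sum by explicit loops (single-count within-network pairs)
bf_within_sum <- function(z, labels, hemis, network, hemi) {
  nidx <- which(labels == network & hemis == hemi)
  hidx <- which(hemis == hemi)
  total <- 0
  counted <- matrix(FALSE, nrow(z), ncol(z))
  for (i in nidx) {
    for (j in hidx) {
      if (i == j) next
      if (labels[j] == network) {
        lo <- min(i, j); hi <- max(i, j)
        if (counted[lo, hi]) next
        counted[lo, hi] <- TRUE
      }
      total <- total + z[i, j]
    }
  }
  total
}

bf_homotopic_sum <- function(z, labels, hemis, network, hemi) {
  nidx <- which(labels == network & hemis == hemi)
  oidx <- which(labels == network & hemis != hemi)
  total <- 0
  for (i in nidx) for (j in oidx) total <- total + z[i, j]
  total
}

bf_whole_contra_sum <- function(z, labels, hemis, network, hemi) {
  nidx <- which(labels == network & hemis == hemi)
  oidx <- which(hemis != hemi)
  total <- 0
  for (i in nidx) for (j in oidx) total <- total + z[i, j]
  total
}

# partial correlation from the negated scaled inverse covariance matrix
bf_partial_cor <- function(x, y, cmat) {
  m <- cbind(x, y, cmat)
  om <- solve(stats::cov(m))
  -om[1, 2] / sqrt(om[1, 1] * om[2, 2])
}

# random symmetric zero-diagonal matrix
rand_sym <- function(n, min = -1, max = 1) {
  m <- matrix(stats::runif(n * n, min, max), n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# planted two-block weighted graph on 2b nodes
planted_two_block <- function(b = 4, w_in = c(0.5, 1), w_out = c(0, 0.3)) {
  n <- 2 * b
  w <- matrix(stats::runif(n * n, w_out[1], w_out[2]), n)
  w[1:b, 1:b] <- stats::runif(b * b, w_in[1], w_in[2])
  w[(b + 1):n, (b + 1):n] <- stats::runif(b * b, w_in[1], w_in[2])
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w
}

# small mirror-paired region table: n_pairs per network, in L-then-R order
toy_regions <- function(networks = c(A = 2, B = 2)) {
  n_pairs <- sum(networks)
  region_table(region_id = 0:(2 * n_pairs - 1),
               hemisphere = rep(c("L", "R"), each = n_pairs),
               pair_index = c(0:(n_pairs - 1), 0:(n_pairs - 1)))
}
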