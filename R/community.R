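# Community detection: seeded weighted Louvain, agreement/consensus
# machinery, the cross-hemisphere symmetric group partition, and
# community-flow tables across age strata.

#' Weighted modularity of a partition
#'
#' Direct evaluation of
#' `Q = (1/2m) * sum_ij (w_ij - gamma * k_i * k_j / 2m) * delta(c_i, c_j)`
#' over all ordered pairs (diagonal null-model terms included).
#'
#' @param w non-negative symmetric weight matrix with zero diagonal.
#' @param membership integer community labels.
#' @param gamma resolution parameter (default 1).
#' @return modularity Q.
#' @export
modularity_q <- function(w, membership, gamma = 1) {
  membership <- partition_labels(membership)
  two_m <- sum(w)
  if (two_m <= 0) stop("total edge weight must be positive")
  k <- rowSums(w)
  q <- 0
  for (c in unique(membership)) {
    idx <- membership == c
    q <- q + sum(w[idx, idx]) / two_m - gamma * (sum(k[idx]) / two_m)^2
  }
  q
}

check_louvain_input <- function(w) {
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop("w must be a square matrix")
  if (any(w < 0)) stop("domain error: negative weights; threshold the matrix first")
  if (max(abs(w - t(w))) > 1e-8) stop("w must be symmetric")
  w <- (w + t(w)) / 2
  diag(w) <- 0
  if (sum(w) <= 0) stop("total edge weight must be positive")
  w
}

#' Louvain community detection
#'
#' Greedy two-phase modularity maximization on a weighted, non-negative
#' graph, with node order shuffled by a seeded RNG each run.  The returned
#' `q` is re-evaluated with [modularity_q()] on the returned partition.
#'
#' @param w non-negative symmetric weight matrix, zero diagonal.
#' @param gamma resolution parameter (default 1).
#' @param seed integer seed; if `NULL`, drawn from the session RNG.
#' @return list with `membership` (1-based labels, first-appearance order)
#'   and `q`.
#' @export
louvain <- function(w, gamma = 1, seed = NULL) {
  w <- check_louvain_input(w)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  membership <- louvain_cpp(w, gamma, as.integer(seed))
  membership <- canonical_labels(membership)
  list(membership = membership, q = modularity_q(w, membership, gamma))
}

#' Best-of-n Louvain
#'
#' Runs [louvain()] `n_runs` times with derived seeds and returns every
#' membership (for agreement building) plus the run with the highest Q.
#'
#' @inheritParams louvain
#' @param n_runs number of repetitions.
#' @param track_best also evaluate Q per run and keep the best? (skipped
#'   when only the agreement matrix is needed).
#' @return list with `memberships` (nodes x runs integer matrix), `best`
#'   (membership of the top-Q run) and `best_q` (both `NULL` when
#'   `track_best = FALSE`).
#' @export
louvain_runs <- function(w, n_runs = 150, gamma = 1, seed = NULL,
                         track_best = TRUE) {
  w <- check_louvain_input(w)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  n <- nrow(w)
  memberships <- matrix(0L, nrow = n, ncol = n_runs)
  best_q <- -Inf
  best <- NULL
  for (r in seq_len(n_runs)) {
    m <- canonical_labels(louvain_cpp(w, gamma, derive_seed(seed, r)))
    memberships[, r] <- m
    if (track_best) {
      q <- modularity_q(w, m, gamma)
      if (q > best_q) { best_q <- q; best <- m }
    }
  }
  if (!track_best) { best <- NULL; best_q <- NULL }
  list(memberships = memberships, best = best, best_q = best_q)
}

#' Agreement (co-assignment) matrix of a set of partitions
#'
#' @param partitions list of label vectors (or a nodes-by-runs matrix).
#' @return symmetric matrix with entries in `[0, 1]` (fraction of runs
#'   co-assigning each node pair), unit diagonal; attribute `n_runs`.
#' @export
agreement <- function(partitions) {
  if (is.list(partitions)) {
    if (length(partitions) == 0) stop("empty partition list")
    lens <- lengths(lapply(partitions, partition_labels))
    if (length(unique(lens)) != 1)
      stop("all partitions must cover the same node set")
    m <- vapply(partitions, partition_labels, integer(lens[1]))
    m <- matrix(m, nrow = lens[1])
  } else {
    m <- as.matrix(partitions)
    storage.mode(m) <- "integer"
  }
  d <- agreement_cpp(m)
  attr(d, "n_runs") <- ncol(m)
  d
}

#' Consensus partition of an agreement matrix
#'
#' Iteratively thresholds the agreement matrix at `tau` (entries below `tau`
#' are zeroed), reruns Louvain `n_runs` times on the thresholded matrix and
#' rebuilds the agreement, until every run returns the identical partition.
#'
#' @param d agreement matrix (entries in `[0, 1]`).
#' @param tau agreement threshold in `[0, 1)` (default 0.5).
#' @param n_runs Louvain repetitions per iteration (default 100).
#' @param gamma resolution parameter.
#' @param seed integer seed.
#' @param max_iter iteration cap (default 50).
#' @return a [partition()].
#' @export
consensus_partition <- function(d, tau = 0.5, n_runs = 100, gamma = 1,
                                seed = NULL, max_iter = 50) {
  if (tau < 0 || tau >= 1) stop("tau must be in [0, 1)")
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  cur <- d
  for (it in seq_len(max_iter)) {
    b <- cur
    b[b < tau] <- 0
    diag(b) <- 0
    if (sum(b) <= 0)
      stop("agreement matrix empty after thresholding at tau = ", tau)
    runs <- louvain_runs(b, n_runs = n_runs, gamma = gamma,
                         seed = derive_seed(seed, it), track_best = FALSE)
    first <- runs$memberships[, 1]
    identical_all <- all(apply(runs$memberships, 2,
                               function(m) all(m == first)))
    if (identical_all) return(partition(first, symmetric = FALSE))
    cur <- agreement(runs$memberships)
  }
  disp <- mean(cur > 0 & cur < 1)
  stop("consensus did not converge after ", max_iter,
       " iterations (agreement dispersion ", signif(disp, 3), ")")
}

#' Symmetric group-level partition across hemispheres
#'
#' For every subject and hemisphere the within-hemisphere thresholded
#' connectivity block is clustered `n_runs_subject` times with Louvain and
#' collapsed to a subject agreement matrix.  Subject agreements are averaged
#' over the cohort per hemisphere; the left and right group matrices
#' (aligned by homotopic pair) are summed and halved; a consensus partition
#' of the result is copied to both hemispheres, so homotopic pairs share
#' labels by construction.
#'
#' @param z_list list of thresholded full-brain z matrices (one per
#'   subject, indexed by included regions in region-table order).
#' @param regions [region_table()].
#' @param gamma resolution parameter.
#' @param n_runs_subject Louvain runs per subject and hemisphere
#'   (default 150).
#' @param n_runs_consensus Louvain runs per consensus iteration
#'   (default 100).
#' @param tau consensus agreement threshold (default 0.5).
#' @param seed integer seed.
#' @return a symmetric [partition()] over included regions.
#' @export
group_symmetric_partition <- function(z_list, regions, gamma = 1,
                                      n_runs_subject = 150,
                                      n_runs_consensus = 100, tau = 0.5,
                                      seed = NULL) {
  if (length(z_list) == 0) stop("empty cohort")
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)
  inc <- included_regions(regions)
  idx_l <- hemi_indices(inc, "L")
  idx_r <- hemi_indices(inc, "R")
  n_pairs <- length(idx_l)
  acc <- list(L = matrix(0, n_pairs, n_pairs), R = matrix(0, n_pairs, n_pairs))
  counter <- 0L
  for (s in seq_along(z_list)) {
    for (hemi in c("L", "R")) {
      idx <- if (hemi == "L") idx_l else idx_r
      wh <- z_list[[s]][idx, idx, drop = FALSE]
      counter <- counter + 1L
      runs <- louvain_runs(wh, n_runs = n_runs_subject, gamma = gamma,
                           seed = derive_seed(seed, counter),
                           track_best = FALSE)
      acc[[hemi]] <- acc[[hemi]] + agreement(runs$memberships)
    }
  }
  d_l <- acc$L / length(z_list)
  d_r <- acc$R / length(z_list)
  d <- (d_l + d_r) / 2  # halved sum keeps entries in [0, 1] for tau
  p_pair <- consensus_partition(d, tau = tau, n_runs = n_runs_consensus,
                                gamma = gamma, seed = derive_seed(seed, -1L))
  labels <- integer(nrow(inc))
  labels[idx_l] <- p_pair$labels
  labels[idx_r] <- p_pair$labels
  partition(labels, symmetric = TRUE)
}

# Greedy maximum-Jaccard matching of partition `p` labels onto reference
# labels; ties broken by lower reference label, then lower p label.
# Unmatched p communities get fresh labels above the reference range.
match_labels_jaccard <- function(ref, p) {
  ref <- partition_labels(ref); p <- partition_labels(p)
  ref_labs <- sort(unique(ref)); p_labs <- sort(unique(p))
  jac <- matrix(0, length(ref_labs), length(p_labs),
                dimnames = list(ref_labs, p_labs))
  for (i in seq_along(ref_labs)) {
    a <- ref == ref_labs[i]
    for (j in seq_along(p_labs)) {
      b <- p == p_labs[j]
      jac[i, j] <- sum(a & b) / sum(a | b)
    }
  }
  mapping <- stats::setNames(rep(NA_integer_, length(p_labs)), p_labs)
  used_ref <- logical(length(ref_labs))
  used_p <- logical(length(p_labs))
  repeat {
    jj <- jac
    jj[used_ref, ] <- -1
    jj[, used_p] <- -1
    best <- max(jj)
    if (best <= 0) break
    hit <- which(jj == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
    mapping[hit[2]] <- ref_labs[hit[1]]
    used_ref[hit[1]] <- TRUE
    used_p[hit[2]] <- TRUE
  }
  nxt <- max(ref_labs) + 1L
  for (j in seq_along(mapping)) {
    if (is.na(mapping[j])) { mapping[j] <- nxt; nxt <- nxt + 1L }
  }
  stats::setNames(mapping[as.character(p)], NULL)
}

#' Community flow across ordered groups
#'
#' Counts, per hemisphere and consecutive group pair, how many regions move
#' from community `a` to community `b`.  Labels are matched across groups by
#' greedy maximum Jaccard overlap (ties to the lower label) so the tables
#' are comparable — the tabular analogue of an alluvial diagram.
#'
#' @param partitions_by_group ordered list of [partition()]s over the same
#'   included-region set (e.g. one per age stratum).
#' @param regions [region_table()].
#' @param group_labels names of the groups (defaults to list names).
#' @return list with `group_labels` and, per hemisphere, matched label
#'   vectors, community counts per group, and the contingency `tables`.
#' @export
community_flow <- function(partitions_by_group, regions,
                           group_labels = names(partitions_by_group)) {
  g <- length(partitions_by_group)
  if (g < 2) stop("need at least two groups")
  if (is.null(group_labels)) group_labels <- paste0("group", seq_len(g))
  inc <- included_regions(regions)
  lens <- vapply(partitions_by_group,
                 function(p) length(partition_labels(p)), integer(1))
  if (any(lens != nrow(inc))) stop("mismatched node sets across groups")
  out <- list(group_labels = group_labels, hemispheres = list())
  for (hemi in c("L", "R")) {
    idx <- which(inc$hemisphere == hemi)
    labs <- lapply(partitions_by_group,
                   function(p) partition_labels(p)[idx])
    matched <- vector("list", g)
    matched[[1]] <- canonical_labels(labs[[1]])
    for (k in 2:g)
      matched[[k]] <- match_labels_jaccard(matched[[k - 1]], labs[[k]])
    tables <- vector("list", g - 1)
    for (k in seq_len(g - 1)) {
      all_labs <- sort(unique(c(matched[[k]], matched[[k + 1]])))
      tables[[k]] <- table(factor(matched[[k]], levels = all_labs),
                           factor(matched[[k + 1]], levels = all_labs))
      names(dimnames(tables[[k]])) <- c("from", "to")
    }
    out$hemispheres[[hemi]] <- list(
      labels = matched,
      n_communities = vapply(matched, function(x) length(unique(x)),
                             integer(1)),
      tables = tables
    )
  }
  out
}
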