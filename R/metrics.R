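# The three hemispheric statistics per (network, hemisphere): summed
# within-hemisphere connectivity, homotopic (inter-hemispheric) sums,
# the segregation ratio, and participation-coefficient based
# intra-hemispheric integration.

net_idx <- function(p, inc, network, hemi) {
  which(partition_labels(p) == network & inc$hemisphere == hemi)
}

#' Within-hemisphere summed connectivity of a network
#'
#' Sum of z values between the nodes of `network` in hemisphere `hemi` and
#' all other nodes of that hemisphere.  Pairs with both ends inside the
#' network are counted once by default (`double_count_within = TRUE` counts
#' them in both directions; the segregation ratio is insensitive to a global
#' convention).
#'
#' @param z full-brain z matrix over included regions (unthresholded by
#'   default in the pipeline).
#' @param p symmetric [partition()].
#' @param regions [region_table()].
#' @param network community label.
#' @param hemi `"L"` or `"R"`.
#' @param double_count_within count within-network pairs twice?
#' @return summed z (`sum_z_within`).
#' @export
within_hemisphere_sum <- function(z, p, regions, network, hemi,
                                  double_count_within = FALSE) {
  inc <- included_regions(regions)
  nidx <- net_idx(p, inc, network, hemi)
  if (length(nidx) == 0)
    stop("network ", network, " empty in hemisphere ", hemi)
  hidx <- which(inc$hemisphere == hemi)
  total <- sum(z[nidx, hidx])  # diagonal is 0; within-pairs counted twice
  if (double_count_within) total else total - sum(z[nidx, nidx]) / 2
}

#' Homotopic (inter-hemispheric) summed connectivity of a network
#'
#' Sum of z values between the nodes of `network` in `hemi` and the nodes of
#' the same community in the opposite hemisphere.  This quantity is also the
#' network's inter-hemispheric integration.
#'
#' @inheritParams within_hemisphere_sum
#' @return summed z (`sum_z_homotopic`).
#' @export
homotopic_sum <- function(z, p, regions, network, hemi) {
  inc <- included_regions(regions)
  nidx <- net_idx(p, inc, network, hemi)
  if (length(nidx) == 0)
    stop("network ", network, " empty in hemisphere ", hemi)
  oidx <- net_idx(p, inc, network, setdiff(c("L", "R"), hemi))
  if (length(oidx) == 0) return(0)
  sum(z[nidx, oidx])
}

#' Inter-hemispheric segregation ratio
#'
#' `(sum_z_within - sum_z_homotopic) / sum_z_within`: 1 when a network has
#' no homotopic connectivity, 0 when its homotopic connectivity equals its
#' within-hemisphere connectivity.
#'
#' @param sum_z_within within-hemisphere sum.
#' @param sum_z_homotopic homotopic sum.
#' @return dimensionless ratio; `NA` with a warning when
#'   `sum_z_within == 0`.
#' @export
hemispheric_segregation <- function(sum_z_within, sum_z_homotopic) {
  out <- (sum_z_within - sum_z_homotopic) / sum_z_within
  undef <- sum_z_within == 0
  if (any(undef)) {
    warning("segregation undefined where sum_z_within == 0; reported as NA")
    out[undef] <- NA_real_
  }
  out
}

#' Summed connectivity of a network to the entire contralateral hemisphere
#'
#' @inheritParams within_hemisphere_sum
#' @return summed z over all contralateral nodes, all networks.
#' @export
whole_contralateral_sum <- function(z, p, regions, network, hemi) {
  inc <- included_regions(regions)
  nidx <- net_idx(p, inc, network, hemi)
  if (length(nidx) == 0)
    stop("network ", network, " empty in hemisphere ", hemi)
  oidx <- which(inc$hemisphere == setdiff(c("L", "R"), hemi))
  sum(z[nidx, oidx])
}

#' Weighted participation coefficients on a hemisphere subgraph
#'
#' `P_i = 1 - sum_s (kappa_is / k_i)^2` where `k_i` is node strength within
#' the hemisphere's (thresholded, non-negative) subgraph and `kappa_is` the
#' strength from `i` to community `s` in that subgraph.  Isolated nodes
#' (`k_i = 0`) get `P_i = 0`.
#'
#' @param z_thresholded thresholded full-brain z matrix over included
#'   regions.
#' @param p symmetric [partition()].
#' @param regions [region_table()].
#' @param hemi `"L"` or `"R"`.
#' @return numeric vector over that hemisphere's nodes (named by
#'   region_id, in region-table order).
#' @export
participation_coefficients <- function(z_thresholded, p, regions, hemi) {
  inc <- included_regions(regions)
  hidx <- which(inc$hemisphere == hemi)
  w <- z_thresholded[hidx, hidx, drop = FALSE]
  if (any(w < 0)) stop("participation requires a non-negative matrix")
  labs <- partition_labels(p)[hidx]
  k <- rowSums(w)
  communities <- unique(labs)
  kappa <- vapply(communities, function(s)
    rowSums(w[, labs == s, drop = FALSE]), numeric(length(hidx)))
  kappa <- matrix(kappa, nrow = length(hidx))
  pc <- ifelse(k > 0, 1 - rowSums((kappa / k)^2), 0)
  stats::setNames(pc, inc$region_id[hidx])
}

#' Intra-hemispheric integration of a network
#'
#' Mean participation coefficient over the network's nodes in one
#' hemisphere.
#'
#' @param pc vector from [participation_coefficients()] for `hemi`.
#' @inheritParams within_hemisphere_sum
#' @return mean participation coefficient.
#' @export
intra_hemispheric_integration <- function(pc, p, regions, network, hemi) {
  inc <- included_regions(regions)
  hidx <- which(inc$hemisphere == hemi)
  sel <- partition_labels(p)[hidx] == network
  if (!any(sel)) stop("network ", network, " empty in hemisphere ", hemi)
  mean(pc[sel])
}

#' Assemble the per-subject network metrics table
#'
#' One row per (network, hemisphere) with the five statistics: the summed
#' sums use the unthresholded z matrix, the participation coefficients the
#' thresholded one.
#'
#' @param z_full unthresholded z matrix over included regions.
#' @param z_thresholded thresholded z matrix (same indexing).
#' @param p symmetric [partition()] (optionally with `network_names`).
#' @param regions [region_table()].
#' @param double_count_within see [within_hemisphere_sum()].
#' @return data.frame with columns network, hemisphere, sum_z_within,
#'   sum_z_homotopic, segregation, inter_integration, intra_integration,
#'   whole_contra_integration.
#' @export
metrics_table <- function(z_full, z_thresholded, p, regions,
                          double_count_within = FALSE) {
  inc <- included_regions(regions)
  labs <- partition_labels(p)
  networks <- sort(unique(labs))
  pcs <- list(L = participation_coefficients(z_thresholded, p, regions, "L"),
              R = participation_coefficients(z_thresholded, p, regions, "R"))
  rows <- list()
  for (network in networks) {
    for (hemi in c("L", "R")) {
      sll <- within_hemisphere_sum(z_full, p, regions, network, hemi,
                                   double_count_within)
      slr <- homotopic_sum(z_full, p, regions, network, hemi)
      name <- if (!is.null(p$network_names) &&
                  as.character(network) %in% names(p$network_names))
        p$network_names[[as.character(network)]] else paste0("C", network)
      rows[[length(rows) + 1]] <- data.frame(
        network = name, hemisphere = hemi,
        sum_z_within = sll, sum_z_homotopic = slr,
        segregation = hemispheric_segregation(sll, slr),
        inter_integration = slr,
        intra_integration = intra_hemispheric_integration(
          pcs[[hemi]], p, regions, network, hemi),
        whole_contra_integration = whole_contralateral_sum(
          z_full, p, regions, network, hemi),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
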