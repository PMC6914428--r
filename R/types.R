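#' Construct and validate a mirror-paired region table
#'
#' The region table declares the parcellation the whole pipeline is indexed
#' by: every region belongs to one hemisphere (`L` or `R`) and is paired with
#' exactly one region at the mirrored position in the opposite hemisphere via
#' `pair_index`.  All connectivity matrices are indexed by the rows of this
#' table (restricted to `included` regions), in table order.
#'
#' @param region_id integer vector of unique non-negative region ids.
#' @param hemisphere character vector of `"L"`/`"R"`.
#' @param pair_index integer vector; each value must occur exactly twice,
#'   once per hemisphere.
#' @param name optional region names.
#' @param included logical; regions retained after screening (default all).
#' @return A `data.frame` of class `region_table`.
#' @export
region_table <- function(region_id, hemisphere, pair_index, name = NULL,
                         included = TRUE) {
  rt <- data.frame(
    region_id = as.integer(region_id),
    hemisphere = as.character(hemisphere),
    pair_index = as.integer(pair_index),
    name = if (is.null(name)) paste0("region_", region_id) else as.character(name),
    included = rep_len(as.logical(included), length(region_id)),
    stringsAsFactors = FALSE
  )
  class(rt) <- c("region_table", "data.frame")
  validate_region_table(rt)
  rt
}

#' @rdname region_table
#' @param rt a putative region table.
#' @export
validate_region_table <- function(rt) {
  req <- c("region_id", "hemisphere", "pair_index", "name", "included")
  if (!all(req %in% names(rt)))
    stop("region table must have columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(rt$region_id))
    stop("region table format error: duplicate region_id")
  if (any(rt$region_id < 0))
    stop("region table format error: region_id must be >= 0")
  if (!all(rt$hemisphere %in% c("L", "R")))
    stop("region table format error: hemisphere must be 'L' or 'R'")
  if (sum(rt$hemisphere == "L") != sum(rt$hemisphere == "R"))
    stop("region table pairing error: unequal L and R region counts")
  tab <- table(rt$pair_index, rt$hemisphere)
  if (!all(dim(tab) == c(nrow(rt) / 2, 2)) || !all(tab == 1L))
    stop("region table pairing error: every pair_index needs exactly one L and one R region")
  invisible(rt)
}

#' Bundle one participant's data
#'
#' @param subject_id character scalar.
#' @param timeseries numeric matrix, `T` timepoints by regions, column order
#'   matching the region table.
#' @param age age in years.
#' @param sex 0/1 coded sex.
#' @param mean_fd mean framewise displacement in mm; if `NULL` it is derived
#'   from `motion` with [mean_framewise_displacement()].
#' @param motion optional `T x 6` rigid-body motion parameter matrix
#'   (3 translations in mm, 3 rotations in radians).
#' @return A list of class `subject_record`.
#' @export
subject_record <- function(subject_id, timeseries, age, sex, mean_fd = NULL,
                           motion = NULL) {
  timeseries <- as.matrix(timeseries)
  if (!is.numeric(timeseries)) stop("timeseries must be numeric")
  if (nrow(timeseries) < 3)
    stop("timeseries needs at least 3 timepoints for correlation")
  if (is.null(mean_fd)) {
    if (is.null(motion))
      stop("either mean_fd or a motion parameter matrix is required")
    mean_fd <- mean_framewise_displacement(motion)
  }
  if (mean_fd < 0) stop("mean_fd must be non-negative")
  structure(
    list(subject_id = as.character(subject_id), timeseries = timeseries,
         age = as.numeric(age), sex = as.integer(sex),
         mean_fd = as.numeric(mean_fd)),
    class = "subject_record"
  )
}

#' Node-to-community partition
#'
#' @param labels integer community labels, one per (included) region, in
#'   region-table order.
#' @param symmetric logical; `TRUE` when homotopic pairs share labels by
#'   construction.
#' @param network_names optional named character vector mapping community
#'   label (as character) to a canonical network name.
#' @return A list of class `partition`.
#' @export
partition <- function(labels, symmetric = FALSE, network_names = NULL) {
  labels <- as.integer(labels)
  if (anyNA(labels)) stop("partition labels must not contain NA")
  structure(list(labels = labels, symmetric = isTRUE(symmetric),
                 network_names = network_names),
            class = "partition")
}

partition_labels <- function(p) {
  if (inherits(p, "partition")) p$labels else as.integer(p)
}

#' Number of non-empty communities in a partition
#'
#' @param p a [partition()] or a plain label vector.
#' @return integer count of distinct labels.
#' @export
count_communities <- function(p) {
  length(unique(partition_labels(p)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same nodes; 1 for
#' identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b partitions or label vectors over the same node set.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  a <- partition_labels(a); b <- partition_labels(b)
  if (length(a) != length(b)) stop("partitions must cover the same node set")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# canonical form: relabel communities 1..K in order of first appearance,
# so label-permuted partitions compare equal
canonical_labels <- function(labels) {
  match(labels, unique(labels))
}

# row indices (into the included-region matrix order) of one hemisphere,
# sorted by pair_index so L and R line up positionally
hemi_indices <- function(regions, hemi, included_only = TRUE) {
  keep <- regions$hemisphere == hemi
  if (included_only) keep <- keep & regions$included
  idx <- which(keep)
  idx[order(regions$pair_index[idx])]
}

# subset a region table to included rows (matrix index space)
included_regions <- function(regions) {
  regions[regions$included, , drop = FALSE]
}
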