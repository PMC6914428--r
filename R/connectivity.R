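# Subject- and region-level screening and construction of Fisher-z
# connectivity matrices, with the two thresholding schemes used downstream.

#' Mean framewise displacement from rigid-body motion parameters
#'
#' Power-style FD: at each timepoint the sum of absolute backward differences
#' of the three translations (mm) and of the three rotations converted to mm
#' of arc on a sphere of `radius` mm.  The first frame contributes 0.
#'
#' @param motion `T x 6` matrix: 3 translations (mm), then 3 rotations (rad).
#' @param radius sphere radius in mm used to convert rotations (default 50).
#' @return mean FD in mm.
#' @export
mean_framewise_displacement <- function(motion, radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("format error: motion must have 6 columns")
  if (nrow(motion) < 2) stop("format error: motion needs at least 2 frames")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radius * rowSums(d[, 4:6, drop = FALSE])
  sum(fd) / nrow(motion)  # first frame contributes 0
}

#' Exclude high-motion subjects
#'
#' @param cohort list of [subject_record()]s.
#' @param fd_max exclusion threshold in mm; subjects with
#'   `mean_fd > fd_max` are removed (default 0.2).
#' @return list with `retained` (subject list) and `excluded`
#'   (data.frame of subject_id, mean_fd).
#' @export
screen_subjects <- function(cohort, fd_max = 0.2) {
  fd <- vapply(cohort, function(s) s$mean_fd, numeric(1))
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  drop <- fd > fd_max
  if (all(drop))
    stop("configuration error: no subjects retained at fd_max = ", fd_max)
  list(retained = cohort[!drop],
       excluded = data.frame(subject_id = ids[drop], mean_fd = fd[drop],
                             stringsAsFactors = FALSE))
}

#' Screen regions by temporal signal-to-noise ratio
#'
#' Region-level SNR is mean(timeseries)/sd(timeseries), averaged over
#' subjects.  Regions whose SNR lies more than `k_sd` standard deviations
#' above or below the mean of the region-level SNR distribution are flagged;
#' a flagged region always excludes its whole homotopic pair.
#'
#' @param cohort list of [subject_record()]s (columns in region-table order).
#' @param regions [region_table()].
#' @param k_sd exclusion bound in s.d. units (default 2).
#' @return list with `report` (data.frame region_id, snr, excluded; plus
#'   attributes `mu`, `sigma`, `excluded_pairs`) and `regions` (updated
#'   table with `included` set).
#' @export
screen_regions_by_snr <- function(cohort, regions, k_sd = 2) {
  if (length(cohort) < 1) stop("at least one subject required")
  if (nrow(regions) < 2) stop("at least two regions required")
  snr_mat <- vapply(cohort, function(s) {
    mu <- colMeans(s$timeseries)
    sdev <- apply(s$timeseries, 2, stats::sd)
    mu / sdev
  }, numeric(nrow(regions)))
  snr_mat <- matrix(snr_mat, nrow = nrow(regions))
  snr <- rowMeans(snr_mat)
  bad <- !is.finite(snr)
  if (any(bad))
    warning("SNR undefined for region(s) ",
            paste(regions$region_id[bad], collapse = ", "),
            " (zero variance); force-excluded")
  mu <- mean(snr[!bad])
  sigma <- stats::sd(snr[!bad])
  if (is.na(sigma)) sigma <- 0
  flag <- bad | (sigma > 0 & (snr > mu + k_sd * sigma |
                                snr < mu - k_sd * sigma))
  if (k_sd == 0 && sigma > 0) flag <- bad | (snr != mu)
  excluded_pairs <- sort(unique(regions$pair_index[flag]))
  out_regions <- regions
  out_regions$included <- !(regions$pair_index %in% excluded_pairs)
  if (!any(out_regions$included))
    stop("SNR screening excluded all regions")
  report <- data.frame(region_id = regions$region_id, snr = snr,
                       excluded = !out_regions$included,
                       stringsAsFactors = FALSE)
  attr(report, "mu") <- mu
  attr(report, "sigma") <- sigma
  attr(report, "excluded_pairs") <- excluded_pairs
  list(report = report, regions = out_regions)
}

#' Fisher z transform
#'
#' `atanh(r)` with `r` clipped to `±(1 - 1e-12)` so perfect correlations map
#' to large finite values.
#'
#' @param r correlations.
#' @param clip clipping bound.
#' @return z values.
#' @export
fisher_z <- function(r, clip = 1 - 1e-12) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Subject-level Fisher-z connectivity matrix
#'
#' Pearson correlation over time between every pair of included regions,
#' Fisher z-transformed, zero diagonal.
#'
#' @param x a [subject_record()] or a `T x regions` numeric matrix.
#' @param regions [region_table()]; only `included` columns are used.
#' @return symmetric z matrix over included regions (attribute
#'   `threshold = "none"`).
#' @export
connectivity_matrix <- function(x, regions) {
  ts <- if (inherits(x, "subject_record")) x$timeseries else as.matrix(x)
  if (nrow(ts) < 3) stop("need at least 3 timepoints")
  if (ncol(ts) != nrow(regions))
    stop("time series columns must match the region table")
  ts <- ts[, regions$included, drop = FALSE]
  sds <- apply(ts, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    inc <- included_regions(regions)
    stop("constant time series for region(s) ",
         paste(inc$region_id[sds == 0 | !is.finite(sds)], collapse = ", "),
         "; run SNR screening first")
  }
  z <- fisher_z(stats::cor(ts))
  diag(z) <- 0
  attr(z, "threshold") <- "none"
  z
}

#' Absolute thresholding of a z matrix
#'
#' Entries strictly greater than `theta` survive with their value; all
#' others (including every negative entry) are set to 0.
#'
#' @param z symmetric z matrix.
#' @param theta threshold (default 0.2); must be non-negative.
#' @return thresholded matrix (attribute `threshold = "absolute(theta)"`).
#' @export
threshold_absolute <- function(z, theta = 0.2) {
  if (theta < 0) stop("configuration error: theta must be >= 0")
  out <- z
  out[out <= theta] <- 0
  diag(out) <- 0
  attr(out, "threshold") <- sprintf("absolute(%g)", theta)
  out
}

#' Proportional (edge-density) thresholding of a z matrix
#'
#' Keeps the `ceiling(density * E)` strongest positive edges (`E` = number
#' of upper-triangle entries); ties at the cutoff weight are all retained.
#' Negative edges are always removed.
#'
#' @param z symmetric z matrix.
#' @param density target edge density in (0, 1].
#' @return thresholded matrix (attribute `threshold = "proportional(d)"`).
#' @export
threshold_proportional <- function(z, density) {
  if (!is.numeric(density) || density <= 0 || density > 1)
    stop("configuration error: density must be in (0, 1]")
  n <- nrow(z)
  ut <- z[upper.tri(z)]
  pos <- ut[ut > 0]
  if (length(pos) == 0) stop("no positive edges to retain")
  n_keep <- min(ceiling(density * length(ut)), length(pos))
  cutoff <- sort(pos, decreasing = TRUE)[n_keep]
  out <- z
  out[out < cutoff] <- 0
  out[out < 0] <- 0
  diag(out) <- 0
  attr(out, "threshold") <- sprintf("proportional(%g)", density)
  out
}
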