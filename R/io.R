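# Readers and writers for the pipeline's plain-text artifacts.  All floats
# are serialized at 12 significant digits so rerunning with the same seed
# reproduces byte-identical files.

fmt_num <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

# write a data.frame as CSV with stable column order and fixed float format
write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = ",", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a region table from delimited text
#'
#' Expects columns `region_id`, `hemisphere`, `pair_index` and optionally
#' `name` and `included`; comma- or tab-separated (auto-detected).
#'
#' @param path file path.
#' @return A validated [region_table()].
#' @export
read_region_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("region_id", "hemisphere", "pair_index")
  if (!all(req %in% names(df)))
    stop("region table format error: need columns ", paste(req, collapse = ", "))
  region_table(df$region_id, df$hemisphere, df$pair_index,
               name = if ("name" %in% names(df)) df$name else NULL,
               included = if ("included" %in% names(df)) df$included else TRUE)
}

#' @rdname read_region_table
#' @param regions a [region_table()].
#' @export
write_region_table <- function(regions, path) {
  write_table_csv(as.data.frame(regions), path)
}

#' Read a parcellated BOLD time-series table
#'
#' The file holds a numeric table with a header of region ids.  By default
#' rows are timepoints and columns are regions; `orientation =
#' "regions-by-time"` reads the transpose (first column = region id).
#' Columns are realigned to region-table order.
#'
#' @param path file path (CSV or TSV).
#' @param regions the [region_table()] declaring the expected regions.
#' @param orientation `"time-by-regions"` (default) or `"regions-by-time"`.
#' @return numeric matrix `T x nrow(regions)`, columns named by region_id.
#' @export
read_timeseries <- function(path, regions,
                            orientation = c("time-by-regions",
                                            "regions-by-time")) {
  orientation <- match.arg(orientation)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = (orientation == "time-by-regions"),
                          sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (orientation == "regions-by-time") {
    ids <- as.integer(df[[1]])
    mat <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(mat) <- ids
    rownames(mat) <- NULL
  } else {
    mat <- as.matrix(df)
    colnames(mat) <- names(df)
  }
  if (!is.numeric(mat)) stop("time-series parse error: non-numeric values")
  ids <- suppressWarnings(as.integer(colnames(mat)))
  if (anyNA(ids)) stop("time-series format error: header must list region ids")
  pos <- match(regions$region_id, ids)
  if (anyNA(pos))
    stop("time-series format error: missing region id(s): ",
         paste(regions$region_id[is.na(pos)], collapse = ", "))
  mat <- mat[, pos, drop = FALSE]
  colnames(mat) <- regions$region_id
  mat
}

#' @rdname read_timeseries
#' @param ts numeric `T x regions` matrix.
#' @export
write_timeseries <- function(ts, regions, path) {
  df <- as.data.frame(ts)
  names(df) <- regions$region_id
  write_table_csv(df, path)
}

#' Average a 4D BOLD array over atlas parcels
#'
#' Operates on in-memory arrays (e.g. loaded from NIfTI by an external tool):
#' `bold` is `nx x ny x nz x T` and `atlas` an integer label volume on the
#' identical voxel grid.  No resampling is performed.
#'
#' @param bold 4D numeric array.
#' @param atlas 3D integer array of parcel labels (0 = background).
#' @param regions [region_table()]; labels are matched as
#'   `region_id + label_offset`.
#' @param label_offset integer added to `region_id` to obtain atlas labels
#'   (default 1, i.e. labels are 1-based).
#' @return `T x nrow(regions)` matrix of parcel-mean time series; empty
#'   parcels give `NaN` columns with a warning.
#' @export
extract_parcel_timeseries <- function(bold, atlas, regions, label_offset = 1L) {
  db <- dim(bold); da <- dim(atlas)
  if (length(db) != 4 || length(da) != 3 || !all(db[1:3] == da))
    stop("geometry error: bold and atlas voxel grids must match")
  labs <- sort(unique(as.integer(atlas)))
  labs <- labs[labs != 0L]
  expected <- regions$region_id + as.integer(label_offset)
  if (!all(labs %in% expected))
    stop("geometry error: atlas label(s) absent from region table: ",
         paste(setdiff(labs, expected), collapse = ", "))
  nt <- db[4]
  vox <- matrix(bold, nrow = prod(db[1:3]), ncol = nt)
  out <- matrix(NA_real_, nrow = nt, ncol = nrow(regions))
  colnames(out) <- regions$region_id
  avec <- as.integer(atlas)
  for (k in seq_len(nrow(regions))) {
    sel <- which(avec == expected[k])
    if (length(sel) == 0L) {
      warning("empty parcel for region_id ", regions$region_id[k],
              "; column set to NaN")
      out[, k] <- NaN
    } else {
      out[, k] <- colMeans(vox[sel, , drop = FALSE])
    }
  }
  out
}

#' Serialize a connectivity matrix with region-id headers
#'
#' @param z symmetric matrix over included regions.
#' @param regions region table (included rows define the order).
#' @param path output CSV path.
#' @export
write_matrix_csv <- function(z, regions, path) {
  inc <- included_regions(regions)
  if (nrow(inc) != nrow(z)) stop("matrix/region dimension mismatch")
  df <- as.data.frame(z)
  names(df) <- inc$region_id
  write_table_csv(df, path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- NULL
  m
}

#' Serialize a partition as JSON
#'
#' Writes `{"region_id": community, ...}` over included regions plus the
#' symmetry flag and any network names.
#'
#' @param p a [partition()].
#' @param regions region table (included rows align with `p$labels`).
#' @param path output path.
#' @export
write_partition_json <- function(p, regions, path) {
  inc <- included_regions(regions)
  if (nrow(inc) != length(p$labels)) stop("partition/region length mismatch")
  obj <- list(
    assignments = stats::setNames(as.list(p$labels), inc$region_id),
    symmetric = p$symmetric,
    network_names = if (is.null(p$network_names)) NULL
                    else as.list(p$network_names)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname write_partition_json
#' @export
read_partition_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nn <- obj$network_names
  if (length(nn) == 0) nn <- NULL else nn <- unlist(nn)
  partition(unlist(obj$assignments), symmetric = isTRUE(obj$symmetric),
            network_names = nn)
}

#' Write association results as CSV
#'
#' @param assoc data.frame returned by [associate_age()] (possibly empty).
#' @param path output path.
#' @export
write_associations <- function(assoc, path) {
  cols <- c("metric", "network", "hemisphere", "n", "r", "p", "p_adjusted",
            "correction", "significant")
  if (nrow(assoc) == 0) {
    writeLines(paste(cols, collapse = ","), path)
    return(invisible(path))
  }
  write_table_csv(assoc[, cols], path)
}

#' Write community-flow contingency tables
#'
#' One CSV per hemisphere per consecutive group pair, named
#' `flow_<hemi>_<from>_to_<to>.csv`, rows = source communities, columns =
#' target communities (labels matched across groups).
#'
#' @param flow result of [community_flow()].
#' @param dir output directory.
#' @return character vector of files written.
#' @export
write_community_flow <- function(flow, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (hemi in names(flow$hemispheres)) {
    tabs <- flow$hemispheres[[hemi]]$tables
    for (i in seq_along(tabs)) {
      fname <- file.path(dir, sprintf("flow_%s_%s_to_%s.csv", hemi,
                                      flow$group_labels[i],
                                      flow$group_labels[i + 1]))
      tab <- tabs[[i]]
      df <- data.frame(from_community = rownames(tab),
                       as.data.frame.matrix(tab), check.names = FALSE)
      write_table_csv(df, fname)
      files <- c(files, fname)
    }
  }
  invisible(files)
}
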