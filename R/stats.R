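# Age-association statistics: partial Pearson correlations with nuisance
# covariates, multiple-comparison correction, and age stratification.

#' Partial Pearson correlation
#'
#' Residualizes `x` and `y` on an intercept plus the covariate columns by
#' least squares and correlates the residuals.  The two-sided p-value uses
#' `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - k` (k covariates).
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame / matrix of covariates, or `NULL` for the
#'   ordinary Pearson correlation.
#' @return list with `r`, `p`, `n`, `df`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y)) stop("missing values in x or y")
  k <- 0L
  if (!is.null(covariates)) {
    cmat <- as.matrix(as.data.frame(covariates))
    if (nrow(cmat) != n) stop("covariate rows must match x")
    if (anyNA(cmat)) stop("missing values in covariates")
    k <- ncol(cmat)
    design <- cbind(1, cmat)
    if (qr(design)$rank < ncol(design))
      stop("rank-deficient covariates (constant or collinear column)")
  } else {
    design <- matrix(1, n, 1)
  }
  if (n <= k + 3) stop("need n > k + 3 observations")
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero residual variance; partial correlation undefined")
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(r = r, p = p, n = n, df = df)
}

#' Multiple-comparison adjustment
#'
#' `bonferroni`: `min(1, m * p)`.  `fdr_bh`: Benjamini-Hochberg step-up with
#' monotonicity enforcement.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"`, `"fdr_bh"` or `"none"`.
#' @param alpha significance level for the flags (default 0.05).
#' @return list with `p_adjusted` and logical `significant`.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "fdr_bh", "none"),
                           alpha = 0.05) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  m <- length(p)
  adj <- switch(method,
    none = p,
    bonferroni = pmin(1, m * p),
    fdr_bh = {
      o <- order(p, decreasing = TRUE)
      ro <- order(o)
      pmin(1, cummin(m / (m:1) * p[o]))[ro]
    })
  list(p_adjusted = adj, significant = adj < alpha)
}

#' Age associations of the network metrics
#'
#' One partial Pearson test of metric vs. age per (network, hemisphere),
#' controlling for sex and mean FD, corrected within metric family:
#' Bonferroni for segregation and inter-hemispheric integration, BH-FDR for
#' intra-hemispheric integration (configurable via `families`).
#'
#' @param metrics_stack data.frame stacking per-subject [metrics_table()]
#'   rows, with a `subject_id` column.
#' @param covariates data.frame with columns `subject_id`, `age` and the
#'   nuisance columns in `control`.
#' @param families named character vector mapping metric column to
#'   correction method.
#' @param control nuisance covariate columns (default sex and mean FD).
#' @param alpha significance level.
#' @return data.frame: metric, network, hemisphere, n, r, p, p_adjusted,
#'   correction, significant.  Degenerate tests (a metric constant across
#'   subjects) yield `NA` r/p with a warning and drop out of the correction
#'   family; `significant` is then `FALSE`.
#' @export
associate_age <- function(metrics_stack, covariates,
                          families = c(segregation = "bonferroni",
                                       inter_integration = "bonferroni",
                                       intra_integration = "fdr_bh"),
                          control = c("sex", "mean_fd"), alpha = 0.05) {
  if (!all(c("subject_id", "age", control) %in% names(covariates)))
    stop("covariates must have subject_id, age and ", paste(control, collapse = ", "))
  out <- list()
  for (metric in names(families)) {
    if (!metric %in% names(metrics_stack)) next
    fam <- list()
    for (network in unique(metrics_stack$network)) {
      for (hemi in unique(metrics_stack$hemisphere)) {
        sub <- metrics_stack[metrics_stack$network == network &
                               metrics_stack$hemisphere == hemi, ]
        if (nrow(sub) == 0) next
        mrg <- merge(sub[, c("subject_id", metric)], covariates,
                     by = "subject_id")
        # a degenerate test (e.g. a metric constant across subjects) is
        # reported as NA rather than aborting the whole family
        res <- tryCatch(
          partial_pearson(mrg[[metric]], mrg$age,
                          mrg[, control, drop = FALSE]),
          error = function(e) {
            warning(metric, " ~ age undefined for ", network, "-", hemi,
                    ": ", conditionMessage(e), call. = FALSE)
            list(r = NA_real_, p = NA_real_, n = nrow(mrg))
          })
        fam[[length(fam) + 1]] <- data.frame(
          metric = metric, network = network, hemisphere = hemi,
          n = res$n, r = res$r, p = res$p, stringsAsFactors = FALSE)
      }
    }
    fam <- do.call(rbind, fam)
    ok <- !is.na(fam$p)
    fam$p_adjusted <- NA_real_
    fam$significant <- FALSE
    if (any(ok)) {
      adj <- adjust_pvalues(fam$p[ok], families[[metric]], alpha)
      fam$p_adjusted[ok] <- adj$p_adjusted
      fam$significant[ok] <- adj$significant
    }
    fam$correction <- families[[metric]]
    fam <- fam[, c("metric", "network", "hemisphere", "n", "r", "p",
                   "p_adjusted", "correction", "significant")]
    out[[metric]] <- fam
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign subjects to the three adult age strata
#'
#' Printed bounds 19-40 / 41-60 / 61-80 are interpreted as
#' `[19, 40.5)`, `[40.5, 60.5)`, `[60.5, 80]` so non-integer ages map to
#' exactly one stratum.  Ages outside `[19, 80]` are rejected (`NA`) with a
#' warning.
#'
#' @param ages numeric vector of ages in years.
#' @return factor with levels `"19-40"`, `"41-60"`, `"61-80"` (`NA` for
#'   out-of-range ages).
#' @export
stratify_by_age <- function(ages) {
  labels <- c("19-40", "41-60", "61-80")
  out_of_range <- ages < 19 | ages > 80
  if (any(out_of_range))
    warning(sum(out_of_range), " age(s) outside [19, 80] rejected")
  g <- findInterval(ages, c(40.5, 60.5)) + 1L
  g[out_of_range] <- NA_integer_
  factor(labels[g], levels = labels)
}
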