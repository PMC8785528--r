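# Data-driven lower-bound thresholds for (Iam_HWE, hiQ).
#
# A hidden bivariate normal is assumed for the index pair (the upper bounds
# of the indices are ignored) and fitted robustly by iterative trimming:
# points whose squared Mahalanobis distance exceeds the chi-square(2)
# quantile at 1 - outlier_alpha are dropped and location/scatter
# re-estimated until the retained set stabilizes. The random region at the
# requested coverage then yields conservative per-index lower bounds: the
# coordinate-wise extremes of the coverage ellipse,
# mu_j - sqrt(chisq(2, coverage) * Sigma[j, j]).

#' Fit a robust bivariate normal to (Iam_HWE, hiQ) and derive thresholds
#'
#' @param metrics Metrics data frame (needs `iam_hwe` and `hiq` columns) or
#'   a two-column numeric matrix. Markers with undefined `iam_hwe` are
#'   excluded from the fit.
#' @param coverage Probability mass of the random region; default
#'   `1 - 1e-9`, conservative enough that false exclusion of a
#'   well-imputed marker is essentially impossible even genome-wide.
#' @param outlier_alpha Trimming tail probability for the chi-square(2)
#'   distance cutoff (default `1e-6`).
#' @param max_iter Maximum trimming iterations.
#' @return Object of class `robust_bivariate_fit`: list with `mu`, `sigma`,
#'   `coverage`, `outlier_alpha`, `iam_lower`, `hiq_lower`,
#'   `n_markers_used`, `n_flagged_outliers`, `iterations`.
#' @export
fit_robust_bivariate <- function(metrics, coverage = 1 - 1e-9,
                                 outlier_alpha = 1e-6, max_iter = 50L) {
  if (!(coverage > 0 && coverage < 1))
    stop("'coverage' must lie in (0, 1)")
  if (!(outlier_alpha > 0 && outlier_alpha < 1))
    stop("'outlier_alpha' must lie in (0, 1)")
  X <- if (is.matrix(metrics)) metrics[, 1:2, drop = FALSE]
       else cbind(metrics$iam_hwe, metrics$hiq)
  colnames(X) <- c("iam", "hiq")
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 10L)
    stop("robust fit needs at least 10 markers with defined Iam_HWE and ",
         "hiQ; got ", nrow(X))

  mu <- apply(X, 2L, stats::median)
  scale0 <- apply(X, 2L, stats::mad)
  for (j in 1:2) {
    if (scale0[[j]] == 0)
      stop("degenerate scatter: coordinate '", colnames(X)[[j]],
           "' has zero robust spread")
  }
  sigma <- diag(scale0^2)
  cutoff <- stats::qchisq(1 - outlier_alpha, df = 2)
  kept_prev <- rep(NA, nrow(X))
  kept <- rep(TRUE, nrow(X))
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    d2 <- stats::mahalanobis(X, mu, sigma)
    kept <- d2 <= cutoff
    if (sum(kept) < 3L)
      stop("robust fit degenerated: fewer than 3 markers retained")
    if (identical(kept, kept_prev)) break
    mu <- colMeans(X[kept, , drop = FALSE])
    sigma <- stats::cov(X[kept, , drop = FALSE])
    for (j in 1:2) {
      if (sigma[j, j] == 0)
        stop("degenerate scatter: coordinate '", colnames(X)[[j]],
             "' has zero variance among retained markers")
    }
    kept_prev <- kept
  }
  r2 <- stats::qchisq(coverage, df = 2)
  structure(
    list(mu = mu, sigma = sigma, coverage = coverage,
         outlier_alpha = outlier_alpha,
         iam_lower = unname(mu[[1L]] - sqrt(r2 * sigma[1L, 1L])),
         hiq_lower = unname(mu[[2L]] - sqrt(r2 * sigma[2L, 2L])),
         n_markers_used = sum(kept),
         n_flagged_outliers = sum(!kept),
         iterations = it),
    class = "robust_bivariate_fit"
  )
}

#' @export
print.robust_bivariate_fit <- function(x, ...) {
  cat("Robust bivariate fit of (Iam_HWE, hiQ)\n",
      sprintf("  robust mean:   Iam = %.4f, hiQ = %.4f\n",
              x$mu[[1L]], x$mu[[2L]]),
      sprintf("  coverage:      %.10g (random region)\n", x$coverage),
      sprintf("  lower bounds:  Iam > %.4f, hiQ > %.4f\n",
              x$iam_lower, x$hiq_lower),
      sprintf("  markers used:  %d (%d trimmed as outliers, %d iterations)\n",
              x$n_markers_used, x$n_flagged_outliers, x$iterations),
      sep = "")
  invisible(x)
}

#' Classify markers against (Iam_HWE, hiQ) thresholds
#'
#' Assigns each marker to one of the four cells of the 2 x 2 table
#' (below/at-or-above each threshold). Markers whose `Iam_HWE` is undefined
#' are classified conservatively as below the Iam threshold; their count is
#' reported separately in attribute `"n_iam_undefined"`.
#'
#' @param metrics Metrics data frame.
#' @param iam_threshold,hiq_threshold Filtering thresholds. The general-use
#'   defaults are 0.5 for `Iam_HWE` and 0.9 for `hiQ`; study-specific
#'   values can be taken from [fit_robust_bivariate()].
#' @param maf_breaks Optional numeric break points for stratifying by the
#'   estimated allele frequency (passed to [cut()] with
#'   `include.lowest = TRUE`).
#' @return Data frame of class `classification_table` with columns
#'   `stratum, iam, hiq, n, prop` (`iam`/`hiq` are `"below"` or `"pass"`;
#'   proportions sum to 1 within each stratum). Attributes record the
#'   thresholds and the undefined-Iam count.
#' @export
classify_markers <- function(metrics, iam_threshold = 0.5,
                             hiq_threshold = 0.9, maf_breaks = NULL) {
  if (!nrow(metrics)) stop("empty metrics table")
  if (!is.finite(iam_threshold) || !is.finite(hiq_threshold))
    stop("thresholds must be finite")
  iam_undef <- is.na(metrics$iam_hwe)
  iam_cell <- ifelse(iam_undef | metrics$iam_hwe < iam_threshold,
                     "below", "pass")
  hiq_cell <- ifelse(is.na(metrics$hiq) | metrics$hiq < hiq_threshold,
                     "below", "pass")
  stratum <- if (is.null(maf_breaks)) {
    factor(rep("all", nrow(metrics)))
  } else {
    cut(metrics$maf_hat, breaks = maf_breaks, include.lowest = TRUE)
  }
  lv <- c("below", "pass")
  tab <- as.data.frame(table(
    stratum = stratum,
    iam = factor(iam_cell, levels = lv),
    hiq = factor(hiq_cell, levels = lv)
  ), responseName = "n", stringsAsFactors = FALSE)
  tot <- stats::ave(tab$n, tab$stratum, FUN = sum)
  tab$prop <- ifelse(tot > 0, tab$n / tot, NA_real_)
  tab <- tab[order(tab$stratum, tab$iam, tab$hiq), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab,
            class = c("classification_table", "data.frame"),
            iam_threshold = iam_threshold, hiq_threshold = hiq_threshold,
            n_iam_undefined = sum(iam_undef))
}

#' Write a classification table as TSV
#'
#' Emits the 2 x 2 cell counts and within-stratum proportions, with the
#' thresholds and the separately-reported undefined-Iam count as comment
#' header lines.
#'
#' @param ct Result of [classify_markers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification_table <- function(ct, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# iam_threshold=%g\thiq_threshold=%g",
            attr(ct, "iam_threshold"), attr(ct, "hiq_threshold")),
    sprintf("# n_iam_undefined=%d", attr(ct, "n_iam_undefined"))
  ), con)
  utils::write.table(as.data.frame(ct), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
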