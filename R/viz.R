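# Diagnostic plots: dual-track Manhattan-like plot of the two indices and
# the (Iam_HWE, hiQ) bubble plot with the robust coverage ellipse.

# cumulative x coordinate across chromosomes, plus per-chromosome offsets
manhattan_coords <- function(metrics) {
  metrics <- sort_metrics(metrics)
  chroms <- unique(metrics$chrom)
  offset <- 0
  offsets <- stats::setNames(numeric(length(chroms)), as.character(chroms))
  x <- numeric(nrow(metrics))
  for (ch in chroms) {
    sel <- metrics$chrom %in% ch
    offsets[[as.character(ch)]] <- offset
    x[sel] <- metrics$position[sel] + offset
    offset <- offset + max(metrics$position[sel]) + 1
  }
  list(metrics = metrics, x = x, offsets = offsets)
}

save_plot_file <- function(p, file, width, height, dpi) {
  tmp <- paste0(file, ".tmp")
  if (grepl("\\.pdf$", file)) {
    grDevices::pdf(tmp, width = width, height = height)
  } else {
    grDevices::png(tmp, width = width * dpi, height = height * dpi,
                   res = dpi)
  }
  print(p)
  grDevices::dev.off()
  file.rename(tmp, file)
  invisible(file)
}

#' Manhattan-like plot of hiQ (upper panel) and Iam_HWE (lower panel)
#'
#' Markers are laid out by cumulative genomic position; the hiQ track is
#' drawn red in the upper panel and the Iam_HWE track blue in the lower
#' panel, each with its filtering threshold as a dashed line. Called
#' hot / very hot regions, when supplied, are shaded.
#'
#' @param metrics Metrics data frame.
#' @param iam_threshold,hiq_threshold Threshold lines (defaults 0.5 / 0.9).
#' @param regions Optional region data frame from
#'   [find_accuracy_regions()].
#' @param file Optional output path (`.png` default, `.pdf` honoured); the
#'   plot object is returned either way.
#' @param width,height,dpi Device geometry (inches / dots per inch).
#' @return The ggplot object, invisibly.
#' @export
plot_manhattan_dual <- function(metrics, iam_threshold = 0.5,
                                hiq_threshold = 0.9, regions = NULL,
                                file = NULL, width = 10, height = 6,
                                dpi = 150) {
  if (is.null(metrics) || !nrow(metrics)) stop("empty metrics table")
  mc <- manhattan_coords(metrics)
  panel_levels <- c("hiQ", "Iam_HWE")
  df <- rbind(
    data.frame(x = mc$x, value = mc$metrics$hiq,
               panel = factor("hiQ", panel_levels)),
    data.frame(x = mc$x, value = mc$metrics$iam_hwe,
               panel = factor("Iam_HWE", panel_levels))
  )
  thr <- data.frame(panel = factor(panel_levels, panel_levels),
                    yintercept = c(hiq_threshold, iam_threshold))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$panel), size = 0.4,
                        na.rm = TRUE, show.legend = FALSE) +
    ggplot2::geom_hline(data = thr,
                        ggplot2::aes(yintercept = .data$yintercept),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(hiQ = "#c0392b",
                                            Iam_HWE = "#2c3e90")) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "cumulative genomic position (bp)", y = "index value",
                  title = "Imputation accuracy along the genome") +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions)) {
    rd <- regions
    rd$panel <- factor(ifelse(rd$metric == "hiq", "hiQ", "Iam_HWE"),
                       panel_levels)
    off <- mc$offsets[as.character(rd$chrom)]
    rd$xmin <- rd$start_bp + off
    rd$xmax <- rd$end_bp + off
    p <- p + ggplot2::geom_rect(
      data = rd, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf,
                   fill = .data$severity), alpha = 0.25) +
      ggplot2::scale_fill_manual(values = c(hot = "orange",
                                            very_hot = "red"))
  }
  if (!is.null(file)) save_plot_file(p, file, width, height, dpi)
  invisible(p)
}

#' Boundary of the robust coverage ellipse
#'
#' Points on the boundary of the random region of a
#' [fit_robust_bivariate()] fit. Its coordinate-wise extremes equal the
#' fit's lower/upper bounds `mu_j +/- sqrt(chisq(2, coverage) * Sigma_jj)`.
#'
#' @param fit A `robust_bivariate_fit`.
#' @param n Number of boundary points.
#' @return Data frame with columns `iam`, `hiq`.
#' @export
coverage_ellipse <- function(fit, n = 721L) {
  stopifnot(inherits(fit, "robust_bivariate_fit"))
  r <- sqrt(stats::qchisq(fit$coverage, df = 2))
  A <- t(chol(fit$sigma))
  theta <- seq(0, 2 * pi, length.out = n)
  pts <- t(fit$mu + r * A %*% rbind(cos(theta), sin(theta)))
  data.frame(iam = pts[, 1L], hiq = pts[, 2L])
}

#' Bubble plot of Iam_HWE against hiQ
#'
#' Markers are aggregated on a fixed grid (default 0.01 x 0.01) and drawn
#' as bubbles whose area scales with the marker count, so the dominant
#' well-imputed mass in the top-right corner does not hide the tail. When a
#' robust fit is supplied its coverage ellipse is overlaid dotted.
#'
#' @param metrics Metrics data frame.
#' @param fit Optional [fit_robust_bivariate()] result.
#' @param bin Grid resolution in index units.
#' @inheritParams plot_manhattan_dual
#' @return The ggplot object, invisibly.
#' @export
plot_bubble <- function(metrics, fit = NULL, bin = 0.01, file = NULL,
                        width = 7, height = 6, dpi = 150) {
  if (is.null(metrics) || !nrow(metrics)) stop("empty metrics table")
  ok <- stats::complete.cases(metrics$iam_hwe, metrics$hiq)
  if (!any(ok)) stop("no markers with defined Iam_HWE and hiQ")
  gx <- round(metrics$iam_hwe[ok] / bin) * bin
  gy <- round(metrics$hiq[ok] / bin) * bin
  agg <- stats::aggregate(list(n = rep(1L, length(gx))),
                          by = list(iam = gx, hiq = gy), FUN = sum)
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$iam, y = .data$hiq)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), shape = 21,
                        fill = "grey60", colour = "grey30", alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::labs(x = "Iam_HWE", y = "hiQ", size = "markers",
                  title = "Iam_HWE by hiQ") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    ell <- coverage_ellipse(fit)
    p <- p + ggplot2::geom_path(data = ell, linetype = "dotted",
                                ggplot2::aes(x = .data$iam, y = .data$hiq))
  }
  if (!is.null(file)) save_plot_file(p, file, width, height, dpi)
  invisible(p)
}
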