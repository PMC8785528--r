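# EWMA smoothing of per-marker indices along each chromosome and calling
# of contiguous low-accuracy ("hot" / "very hot") regions.

#' One-sided exponentially weighted moving average
#'
#' Causal recursion `s_1 = x_1; s_t = alpha * x_t + (1 - alpha) * s_{t-1}`
#' in the order given. `NA` entries are transparent: the smoothing state is
#' carried across them and they receive `NA` in the output.
#'
#' @param x Numeric series ordered by genomic position.
#' @param alpha Smoothing factor in (0, 1\]; 0.1 is the conventional value
#'   for genome scans, 1 reproduces the raw series.
#' @return Numeric vector, same length as `x`.
#' @export
ewma_smooth <- function(x, alpha = 0.1) {
  if (!length(x)) stop("empty series")
  if (!(alpha > 0 && alpha <= 1)) stop("'alpha' must lie in (0, 1]")
  s <- rep(NA_real_, length(x))
  idx <- which(!is.na(x))
  if (length(idx)) {
    xs <- x[idx]
    s[idx] <- as.numeric(stats::filter(alpha * xs, 1 - alpha,
                                       method = "recursive",
                                       init = xs[[1L]]))
  }
  s
}

# runs of TRUE in a logical vector -> list of (start_index, end_index)
runs_of <- function(flag) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

empty_regions <- function() {
  data.frame(chrom = character(), start_bp = integer(), end_bp = integer(),
             n_variants = integer(), metric = character(),
             severity = character(), min_smoothed = numeric(),
             stringsAsFactors = FALSE)
}

#' Call hot / very hot regions on one smoothed track
#'
#' A hot region is a maximal run of consecutive markers whose smoothed
#' index is strictly below `threshold`; very hot regions are, independently,
#' maximal runs strictly below `threshold * very_hot_factor` (they may nest
#' inside hot regions and are reported separately). Region bounds are the
#' positions of the first and last member marker (1-based closed);
#' single-marker regions are allowed.
#'
#' @param track Data frame for a single chromosome with columns `chrom`,
#'   `position` (strictly increasing) and `smoothed`.
#' @param threshold Hot cutoff applied to the smoothed index.
#' @param very_hot_factor Multiplier giving the very-hot cutoff
#'   (default 0.5).
#' @param metric Label recorded in the output (e.g. `"iam_hwe"`).
#' @return Data frame with one row per region: `chrom, start_bp, end_bp,
#'   n_variants, metric, severity, min_smoothed`.
#' @export
call_regions <- function(track, threshold, very_hot_factor = 0.5,
                         metric = "index") {
  if (!is.finite(threshold)) stop("'threshold' must be finite")
  stopifnot(all(c("chrom", "position", "smoothed") %in% names(track)))
  if (nrow(track) > 1L && any(diff(track$position) <= 0))
    stop("positions must be strictly increasing within a chromosome")
  out <- empty_regions()
  cuts <- c(hot = threshold, very_hot = threshold * very_hot_factor)
  for (sev in names(cuts)) {
    rr <- runs_of(track$smoothed < cuts[[sev]])
    if (!nrow(rr)) next
    rows <- data.frame(
      chrom = track$chrom[rr[, "start"]],
      start_bp = track$position[rr[, "start"]],
      end_bp = track$position[rr[, "end"]],
      n_variants = rr[, "end"] - rr[, "start"] + 1L,
      metric = metric, severity = sev,
      min_smoothed = vapply(seq_len(nrow(rr)), function(k) {
        min(track$smoothed[rr[k, "start"]:rr[k, "end"]], na.rm = TRUE)
      }, numeric(1L)),
      stringsAsFactors = FALSE
    )
    out <- rbind(out, rows)
  }
  out
}

#' Scan a metrics table for low-accuracy regions
#'
#' Orders markers by position within each chromosome, smooths the chosen
#' index with a one-sided EWMA (restarted per chromosome) and calls hot and
#' very hot regions. Markers with an undefined index carry the smoothing
#' state but cannot belong to a region.
#'
#' @param metrics Metrics data frame.
#' @param metric Which index to scan: `"iam_hwe"` or `"hiq"`.
#' @param threshold Hot cutoff on the smoothed index (defaults: 0.5 for
#'   `iam_hwe`, 0.9 for `hiq`).
#' @param smoothing_factor EWMA smoothing factor (default 0.1).
#' @param very_hot_factor Very-hot cutoff multiplier (default 0.5).
#' @param reverse Also run the EWMA in descending position order and keep a
#'   marker-level union of regions? Off by default; intended for
#'   sensitivity analysis of the causal-pass direction.
#' @return Region data frame as in [call_regions()], position-ordered
#'   within severity; the smoothed tracks are attached as attribute
#'   `"tracks"`.
#' @export
find_accuracy_regions <- function(metrics, metric = c("iam_hwe", "hiq"),
                                  threshold = NULL, smoothing_factor = 0.1,
                                  very_hot_factor = 0.5, reverse = FALSE) {
  metric <- match.arg(metric)
  if (is.null(threshold))
    threshold <- if (metric == "iam_hwe") 0.5 else 0.9
  if (!nrow(metrics)) stop("empty metrics table")
  metrics <- sort_metrics(metrics)
  regions <- empty_regions()
  tracks <- list()
  for (ch in unique(metrics$chrom)) {
    sub <- metrics[metrics$chrom %in% ch, , drop = FALSE]
    raw <- sub[[metric]]
    smoothed <- ewma_smooth(raw, smoothing_factor)
    if (reverse) {
      back <- rev(ewma_smooth(rev(raw), smoothing_factor))
      smoothed <- pmin(smoothed, back)
    }
    track <- data.frame(chrom = sub$chrom, position = sub$position,
                        raw = raw, smoothed = smoothed,
                        stringsAsFactors = FALSE)
    tracks[[as.character(ch)]] <- track
    regions <- rbind(regions,
                     call_regions(track, threshold, very_hot_factor, metric))
  }
  regions <- regions[order(regions$severity,
                           chrom_rank(regions$chrom),
                           regions$start_bp), , drop = FALSE]
  rownames(regions) <- NULL
  attr(regions, "tracks") <- tracks
  attr(regions, "threshold") <- threshold
  attr(regions, "smoothing_factor") <- smoothing_factor
  regions
}

#' Summarize called regions
#'
#' @param regions Region data frame from [find_accuracy_regions()] or
#'   [call_regions()].
#' @return Data frame with one row per (metric, severity): region count,
#'   total variants, fraction of singleton regions and size quantiles
#'   (min / median / 90th percentile / max).
#' @export
summarize_regions <- function(regions) {
  if (!nrow(regions)) {
    return(data.frame(metric = character(), severity = character(),
                      n_regions = integer(), n_variants_total = integer(),
                      fraction_singleton = numeric(), size_min = integer(),
                      size_median = numeric(), size_p90 = numeric(),
                      size_max = integer(), stringsAsFactors = FALSE))
  }
  grp <- interaction(regions$metric, regions$severity, drop = TRUE)
  do.call(rbind, lapply(levels(grp), function(g) {
    sz <- regions$n_variants[grp == g]
    data.frame(
      metric = regions$metric[grp == g][[1L]],
      severity = regions$severity[grp == g][[1L]],
      n_regions = length(sz),
      n_variants_total = sum(sz),
      fraction_singleton = mean(sz == 1L),
      size_min = min(sz),
      size_median = stats::median(sz),
      size_p90 = unname(stats::quantile(sz, 0.9)),
      size_max = max(sz),
      stringsAsFactors = FALSE
    )
  }))
}

#' Write called regions to disk
#'
#' Default output is a BED-like TSV in 1-based closed coordinates with an
#' explicit header comment saying so; `bed = TRUE` writes a true BED file
#' (0-based half-open, no header) instead.
#'
#' @param regions Region data frame.
#' @param path Output path.
#' @param bed Write standard BED coordinates?
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, bed = FALSE) {
  if (bed) {
    df <- data.frame(chrom = regions$chrom,
                     start = regions$start_bp - 1L,
                     end = regions$end_bp,
                     name = sprintf("%s_%s", regions$metric,
                                    regions$severity),
                     score = regions$n_variants,
                     strand = ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("# coordinates: 1-based, closed intervals", con)
  df <- regions[, c("chrom", "start_bp", "end_bp", "metric", "severity",
                    "min_smoothed", "n_variants")]
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
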