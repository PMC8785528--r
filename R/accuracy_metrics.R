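# Per-marker accuracy indices computed from a-posteriori genotype
# probability triplets (p0, p1, p2), one triplet per individual.
#
# Allele dose d = 0*p0 + 1*p1 + 2*p2 counts the B (second / alternative)
# allele. All indices are symmetric under reversing the triplet orientation,
# so the allele the dose counts is immaterial.

drop_missing_rows <- function(probs) {
  if (!is.matrix(probs) || ncol(probs) != 3L)
    stop("'probs' must be an N x 3 matrix")
  probs[stats::complete.cases(probs), , drop = FALSE]
}

#' Estimate the dose-counted allele frequency from dosages
#'
#' The frequency of the dose-counted allele is estimated by averaging the
#' allele doses d_i = p1 + 2 p2 across individuals: f-hat = sum(d) / (2 N).
#' Suitable for case-control and cross-sectional samples; for family data
#' restrict `probs` to unrelated founders first.
#'
#' @param probs N x 3 matrix of genotype probability triplets; `NA` rows
#'   (excluded individuals) are ignored.
#' @return Estimated allele frequency in \[0, 1\]. Unfolded: values above
#'   0.5 are returned as-is.
#' @export
estimate_allele_freq <- function(probs) {
  probs <- drop_missing_rows(probs)
  n <- nrow(probs)
  if (n == 0L) stop("no usable individuals: all dosage triplets are missing")
  d <- probs[, 2L] + 2 * probs[, 3L]
  sum(d) / (2 * n)
}

#' Anti-concentration Q of a dosage triplet
#'
#' Q = sum_g p_g (1 - p_g), the complement of the Herfindahl-Hirschman
#' concentration of the triplet: 0 for a one-hot triplet (fully
#' individual-specific information), 2/3 for the uniform triplet
#' (1/3, 1/3, 1/3) (pure chance). For normalized triplets this equals
#' 1 - sum p_g^2.
#'
#' @param triplet Numeric vector of length 3, or an N x 3 matrix for
#'   row-wise evaluation.
#' @return Q in \[0, 2/3\] (scalar or vector).
#' @export
anti_concentration <- function(triplet) {
  if (is.matrix(triplet)) {
    if (ncol(triplet) != 3L) stop("'triplet' matrix must have 3 columns")
    return(rowSums(triplet * (1 - triplet)))
  }
  if (length(triplet) != 3L) stop("'triplet' must have length 3")
  sum(triplet * (1 - triplet))
}

#' Anti-concentration of the Hardy-Weinberg dosage triplet
#'
#' Closed form of Q evaluated at the HWE genotype distribution implied by
#' allele frequency `f`:
#' `Q_HWE(f) = (-2 f) (f - 1) (3 f^2 - 3 f + 2)`.
#' Symmetric under `f <-> 1 - f`, zero at `f` in `{0, 1}`, maximal (0.625)
#' at `f = 0.5`.
#'
#' @param f Allele frequency (vectorized) in \[0, 1\].
#' @return Q_HWE in \[0, 0.625\].
#' @export
q_hwe <- function(f) {
  if (any(is.na(f)) || any(f < 0 | f > 1))
    stop("allele frequency must lie in [0, 1]")
  (-2 * f) * (f - 1) * (3 * f^2 - 3 * f + 2)
}

#' Chance-anchored information index Iam_chance
#'
#' Linear rescaling of the marker-mean anti-concentration:
#' `Iam_chance = 1 - q_bar / (2/3)`. Equals 1 when every triplet is one-hot
#' and 0 when every triplet is uniform.
#'
#' @param q_bar Mean anti-concentration in \[0, 2/3\] (vectorized).
#' @return Index in \[0, 1\].
#' @export
iam_chance <- function(q_bar) {
  if (any(is.na(q_bar)) || any(q_bar < -1e-9 | q_bar > 2 / 3 + 1e-9))
    stop("'q_bar' must lie in [0, 2/3]")
  pmin(pmax(1 - q_bar / (2 / 3), 0), 1)
}

#' HWE-anchored information index Iam_HWE
#'
#' `Iam_HWE = 1 - q_bar / Q_HWE(f)`: 1 for one-hot dosages, 0 when the
#' dosages carry exactly the information of the HWE genotype distribution
#' at frequency `f` (purely population-specific information). Negative
#' values occur when triplets sit between the uniform and the HWE triplet
#' and are returned unmodified; small negative values can arise by chance.
#' When `Q_HWE(f) = 0` (monomorphic, `f` in `{0, 1}`) the index is
#' undefined and `NA` is returned.
#'
#' @param q_bar Mean anti-concentration in \[0, 2/3\].
#' @param f Estimated allele frequency in \[0, 1\].
#' @return Index <= 1, possibly negative, or `NA` when undefined.
#' @export
iam_hwe <- function(q_bar, f) {
  qh <- q_hwe(f)
  out <- ifelse(qh > 0, 1 - q_bar / qh, NA_real_)
  if (length(out) == 1L) out <- as.numeric(out)
  out
}

#' Average-dosage distribution of a marker
#'
#' Component-wise mean of the dosage triplets across individuals; a
#' trinomial distribution over the three genotypes.
#'
#' @inheritParams estimate_allele_freq
#' @return Numeric 3-vector summing to 1.
#' @export
average_dosage_dist <- function(probs) {
  probs <- drop_missing_rows(probs)
  if (nrow(probs) == 0L)
    stop("no usable individuals: all dosage triplets are missing")
  colMeans(probs)
}

#' Average best-guess distribution of a marker
#'
#' Each individual contributes a one-hot vector at its maximal-probability
#' genotype; ties split the mass equally among the tied genotypes, so the
#' result is a deterministic proper distribution. The returned vector is
#' the mean of these contributions.
#'
#' @inheritParams estimate_allele_freq
#' @return Numeric 3-vector summing to 1.
#' @export
best_guess_dist <- function(probs) {
  probs <- drop_missing_rows(probs)
  if (nrow(probs) == 0L)
    stop("no usable individuals: all dosage triplets are missing")
  mx <- pmax(probs[, 1L], probs[, 2L], probs[, 3L])
  is_max <- probs == mx  # ties share the row's unit mass equally
  w <- is_max / rowSums(is_max)
  colMeans(w)
}

#' Heterogeneity-in-quantities index hiQ
#'
#' One minus the Hellinger distance between the average-dosage distribution
#' and the average best-guess distribution:
#' `hiQ = 1 - sqrt(1 - sum_g sqrt(f_ad(g) * f_bg(g)))`.
#' Equals 1 iff the two distributions coincide (full inter-individual
#' heterogeneity is visible to statistical tests) and 0 when they are
#' perpendicular.
#'
#' @param f_ad,f_bg Probability 3-vectors (each sums to 1 within `1e-6`).
#' @return Index in \[0, 1\].
#' @export
hiq <- function(f_ad, f_bg) {
  for (v in list(f_ad, f_bg)) {
    if (length(v) != 3L || any(is.na(v)) || any(v < 0) ||
        abs(sum(v) - 1) > 1e-6)
      stop("'f_ad' and 'f_bg' must be probability 3-vectors")
  }
  # Bhattacharyya coefficient; clip fp overshoot before the outer sqrt
  bc <- min(sum(sqrt(f_ad * f_bg)), 1)
  1 - sqrt(1 - bc)
}

#' Compute all accuracy metrics for one marker
#'
#' Applies missing-individual exclusion, then computes the estimated allele
#' frequency, mean anti-concentration, both Iam rescalings and hiQ.
#'
#' @param x A [marker_record()] or a bare N x 3 probability matrix.
#' @return One-row data frame with columns
#'   `snp_id, rs_id, chrom, position, maf_hat, q_bar, iam_chance, iam_hwe,
#'   hiq, n_used, flags` (flags as a `;`-separated string, `""` if none).
#' @export
compute_marker <- function(x) {
  if (is.matrix(x))
    x <- marker_record("marker", "marker", NA_character_, 1L, "A", "B", x)
  if (!inherits(x, "marker_record"))
    stop("'x' must be a marker_record or an N x 3 probability matrix")
  probs <- drop_missing_rows(x$probs)
  flags <- x$flags
  if (nrow(probs) == 0L) {
    row <- data.frame(
      snp_id = x$snp_id, rs_id = x$rs_id, chrom = x$chrom,
      position = x$position, maf_hat = NA_real_, q_bar = NA_real_,
      iam_chance = NA_real_, iam_hwe = NA_real_, hiq = NA_real_,
      n_used = 0L, flags = paste(unique(c(flags, FLAG_MISSING_EXCLUDED)),
                                 collapse = ";"),
      stringsAsFactors = FALSE
    )
    return(row)
  }
  f_hat <- estimate_allele_freq(probs)
  q_bar <- mean(anti_concentration(probs))
  i_hwe <- iam_hwe(q_bar, f_hat)
  if (is.na(i_hwe)) flags <- c(flags, FLAG_IAM_HWE_UNDEFINED)
  data.frame(
    snp_id = x$snp_id, rs_id = x$rs_id, chrom = x$chrom,
    position = x$position,
    maf_hat = f_hat, q_bar = q_bar,
    iam_chance = iam_chance(q_bar), iam_hwe = i_hwe,
    hiq = hiq(average_dosage_dist(probs), best_guess_dist(probs)),
    n_used = nrow(probs),
    flags = paste(unique(flags), collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Compute the metrics table for a set of marker records
#'
#' @param records List of [marker_record()] objects.
#' @return Metrics data frame, one row per marker, sorted by
#'   (chromosome, position).
#' @export
compute_metrics <- function(records) {
  if (!length(records)) stop("no marker records supplied")
  rows <- lapply(records, compute_marker)
  sort_metrics(do.call(rbind, rows))
}

#' Stream a GEN file into a metrics table
#'
#' Parses and scores one marker at a time, so memory use is bounded per
#' marker regardless of file size.
#'
#' @inheritParams stream_gen
#' @param sample_path Optional companion SAMPLE file; when given, the
#'   individual count is cross-checked against every GEN line.
#' @return Metrics data frame sorted by (chromosome, position), with the
#'   sample size recorded in attribute `"n_individuals"`.
#' @export
compute_gen_metrics <- function(path, sample_path = NULL,
                                chrom = NA_character_,
                                policy = c("strict", "lenient"),
                                tol = 1e-3) {
  policy <- match.arg(policy)
  expected_n <- NULL
  if (!is.null(sample_path)) expected_n <- read_sample_file(sample_path)$n
  rows <- stream_gen(path, compute_marker, expected_n = expected_n,
                     chrom = chrom, policy = policy, tol = tol)
  if (!length(rows)) stop("no markers found in '", path, "'")
  metrics <- sort_metrics(do.call(rbind, rows))
  attr(metrics, "n_individuals") <-
    if (!is.null(expected_n)) expected_n else NA_integer_
  metrics
}
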