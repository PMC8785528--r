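# Synthetic dosage generator.
#
# Each individual's true genotype G is drawn from HWE at the marker's
# allele frequency f; the emitted triplet is the mixture
#   lambda * onehot(G) + (1 - lambda) * B
# where B is the blur distribution: the HWE triplet at f ("hwe"), the
# uniform triplet ("uniform"), or one fixed random triplet shared by all
# individuals of the marker ("homogeneous"). The three marginal accuracy
# situations -- fully individual-specific (lambda = 1), pure chance
# (lambda = 0, uniform blur) and purely population-specific (lambda = 0,
# HWE blur) -- are exact endpoints of the mixture, so endpoint behaviour
# of the indices is analytically forced rather than calibrated.

#' MAF laws for the synthetic generator
#'
#' `maf_law_fixed()` gives every marker the same frequency;
#' `maf_law_uniform()` draws uniformly from a range; and
#' `maf_law_low_enriched()` draws from a rare-variant-enriched mixture
#' (default composition: 50% of markers with f in \[1e-4, 0.01), 15% in
#' \[0.01, 0.05) and 35% in \[0.05, 0.5\]) as seen on imputation backbones
#' enriched for low-frequency variants.
#'
#' @param value,min,max Frequency value / range in \[0, 1\].
#' @param p_rare,p_low Mixture weights of the rare and low-frequency
#'   components (the common component takes the remainder).
#' @return A `maf_law` object usable in [simulation_config()].
#' @export
maf_law_fixed <- function(value = 0.2) {
  stopifnot(value >= 0, value <= 1)
  structure(list(type = "fixed", value = value), class = "maf_law")
}

#' @rdname maf_law_fixed
#' @export
maf_law_uniform <- function(min = 0.01, max = 0.5) {
  stopifnot(min >= 0, max <= 1, min < max)
  structure(list(type = "uniform", min = min, max = max),
            class = "maf_law")
}

#' @rdname maf_law_fixed
#' @export
maf_law_low_enriched <- function(p_rare = 0.5, p_low = 0.15) {
  stopifnot(p_rare >= 0, p_low >= 0, p_rare + p_low <= 1)
  structure(list(type = "low_enriched", p_rare = p_rare, p_low = p_low),
            class = "maf_law")
}

draw_maf <- function(law, n) {
  switch(law$type,
    fixed = rep(law$value, n),
    uniform = stats::runif(n, law$min, law$max),
    low_enriched = {
      comp <- sample.int(3L, n, replace = TRUE,
                         prob = c(law$p_rare, law$p_low,
                                  1 - law$p_rare - law$p_low))
      lo <- c(1e-4, 0.01, 0.05)[comp]
      hi <- c(0.01, 0.05, 0.5)[comp]
      stats::runif(n, lo, hi)
    },
    stop("unknown MAF law type '", law$type, "'")
  )
}

#' Simulation configuration for synthetic dosage data
#'
#' @param n_individuals,n_markers Dataset dimensions.
#' @param maf_law A `maf_law` object (see [maf_law_fixed()]); default is
#'   the low-frequency-enriched mixture.
#' @param accuracy_lambda Imputation accuracy in \[0, 1\]: weight of the
#'   true-genotype one-hot component of every triplet. Scalar (global) or
#'   one value per marker.
#' @param blur_mode `"hwe"`, `"uniform"` or `"homogeneous"`.
#' @param hot_region_spec Optional list (or list of lists) with fields
#'   `start` (first marker index), `n` (marker count) and `lambda`
#'   (accuracy assigned inside the span) planting a contiguous low-accuracy
#'   region. Spans must not overlap.
#' @param chrom Chromosome label written to the records.
#' @param seed Integer RNG seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_individuals = 1000L, n_markers = 200L,
                              maf_law = maf_law_low_enriched(),
                              accuracy_lambda = 0.95,
                              blur_mode = c("hwe", "uniform", "homogeneous"),
                              hot_region_spec = NULL, chrom = "1",
                              seed = 1L) {
  blur_mode <- match.arg(blur_mode)
  stopifnot(n_individuals >= 1L, n_markers >= 1L,
            inherits(maf_law, "maf_law"),
            all(accuracy_lambda >= 0), all(accuracy_lambda <= 1),
            length(accuracy_lambda) %in% c(1L, n_markers))
  if (!is.null(hot_region_spec)) {
    if (!is.null(hot_region_spec$start)) hot_region_spec <-
        list(hot_region_spec)
    spans <- lapply(hot_region_spec, function(h) {
      stopifnot(is.numeric(h$start), is.numeric(h$n),
                h$lambda >= 0, h$lambda <= 1)
      if (h$start < 1L || h$start + h$n - 1L > n_markers)
        stop("hot-region span [", h$start, ", ", h$start + h$n - 1L,
             "] falls outside the ", n_markers, " markers")
      seq(h$start, h$start + h$n - 1L)
    })
    if (anyDuplicated(unlist(spans)))
      stop("hot-region spans overlap")
  }
  structure(
    list(n_individuals = as.integer(n_individuals),
         n_markers = as.integer(n_markers), maf_law = maf_law,
         accuracy_lambda = accuracy_lambda, blur_mode = blur_mode,
         hot_region_spec = hot_region_spec, chrom = as.character(chrom),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

hwe_triplet <- function(f) c((1 - f)^2, 2 * f * (1 - f), f^2)

#' Simulate one marker's dosage triplets
#'
#' Draws `n` true genotypes from HWE at frequency `f` and blurs the one-hot
#' triplets toward the blur distribution with weight `1 - lambda`. Uses the
#' current RNG state; seed management belongs to the caller (or to
#' [simulate_dataset()]).
#'
#' @param f Allele frequency of the dose-counted allele, in \[0, 1\].
#' @param n Number of individuals.
#' @param lambda Accuracy weight in \[0, 1\].
#' @param blur_mode `"hwe"`, `"uniform"` or `"homogeneous"`.
#' @param blur_triplet Triplet used for `"homogeneous"` blur; drawn
#'   uniformly on the simplex when omitted.
#' @return N x 3 matrix of dosage triplets (rows sum to 1 by construction).
#' @export
simulate_marker <- function(f, n, lambda,
                            blur_mode = c("hwe", "uniform", "homogeneous"),
                            blur_triplet = NULL) {
  blur_mode <- match.arg(blur_mode)
  if (is.na(f) || f < 0 || f > 1) stop("'f' must lie in [0, 1]")
  if (is.na(lambda) || lambda < 0 || lambda > 1)
    stop("'lambda' must lie in [0, 1]")
  g <- sample(0:2, n, replace = TRUE, prob = hwe_triplet(f))
  onehot <- matrix(0, n, 3L)
  onehot[cbind(seq_len(n), g + 1L)] <- 1
  blur <- switch(blur_mode,
    hwe = hwe_triplet(f),
    uniform = rep(1 / 3, 3L),
    homogeneous = {
      if (is.null(blur_triplet)) {
        u <- -log(stats::runif(3L))  # uniform on the simplex
        blur_triplet <- u / sum(u)
      }
      blur_triplet
    })
  lambda * onehot + (1 - lambda) * matrix(blur, n, 3L, byrow = TRUE)
}

#' Simulate a full synthetic dosage dataset
#'
#' Reproducible for a fixed configuration: the RNG is seeded from
#' `config$seed` (and restored afterwards). Marker positions are strictly
#' increasing; markers inside a planted hot-region span receive the span's
#' low accuracy.
#'
#' @param config A [simulation_config()].
#' @return List with `records` (list of [marker_record()]), `sample_ids`,
#'   `maf` and `lambda` (the per-marker values actually used), and
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()))
  }
  set.seed(config$seed)
  M <- config$n_markers
  n <- config$n_individuals
  maf <- draw_maf(config$maf_law, M)
  lambda <- rep(config$accuracy_lambda, length.out = M)
  if (!is.null(config$hot_region_spec)) {
    for (h in config$hot_region_spec)
      lambda[seq(h$start, h$start + h$n - 1L)] <- h$lambda
  }
  positions <- cumsum(sample(1000:5000, M, replace = TRUE))
  records <- vector("list", M)
  for (m in seq_len(M)) {
    probs <- simulate_marker(maf[[m]], n, lambda[[m]], config$blur_mode)
    records[[m]] <- marker_record(
      snp_id = sprintf("snp%05d", m), rs_id = sprintf("rs%07d", m),
      chrom = config$chrom, position = positions[[m]],
      allele_a = "A", allele_b = "B", probs = probs
    )
  }
  list(records = records,
       sample_ids = sprintf("sample%04d", seq_len(n)),
       maf = maf, lambda = lambda, config = config)
}

format_probs <- function(p) {
  # full precision so that parsing reproduces the triplets bit-exactly
  sub("^1$", "1", formatC(p, digits = 17, format = "g"))
}

#' Write marker records as a GEN file
#'
#' Probabilities are written at full precision (17 significant digits) so
#' that a read-back reproduces the generating triplets exactly. Gzip output
#' is selected by a `.gz` suffix.
#'
#' @param records List of [marker_record()] objects.
#' @param path Output path (`.gz` for compressed output).
#' @return `path`, invisibly.
#' @export
write_gen <- function(records, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (rec in records) {
    p <- rec$probs
    p[is.na(p)] <- 0  # missing individuals: the all-zero convention
    writeLines(paste(rec$snp_id, rec$rs_id, rec$position,
                     rec$allele_a, rec$allele_b,
                     paste(format_probs(as.vector(t(p))), collapse = " ")),
               con)
  }
  invisible(path)
}

#' Write a SAMPLE companion file
#'
#' @param sample_ids Ordered individual identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample <- function(sample_ids, path) {
  lines <- c("ID_1 ID_2 missing", "0 0 0",
             paste(sample_ids, sample_ids, "0"))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a dataset and write GEN/SAMPLE files
#'
#' @param config A [simulation_config()].
#' @param gen_path,sample_path Output paths.
#' @return The [simulate_dataset()] result, invisibly.
#' @export
simulate_to_files <- function(config, gen_path, sample_path) {
  sim <- simulate_dataset(config)
  write_gen(sim$records, gen_path)
  write_sample(sim$sample_ids, sample_path)
  invisible(sim)
}
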