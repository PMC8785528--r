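# Optional VCF input: markers with a per-genotype probability field (GP).

#' Read markers with genotype probabilities from a VCF
#'
#' Extracts the `GP` FORMAT field (a-posteriori genotype probabilities in
#' VCF order hom-ref, het, hom-alt) of a biallelic VCF into marker
#' records, mapping the triplet to (p0, p1, p2) with the dose counting the
#' alternative allele. Since every index is symmetric under triplet
#' reversal, the orientation convention has no effect on the metrics.
#' Individuals with a missing `GP` entry are excluded and flagged.
#' Requires the suggested `vcfR` package.
#'
#' @param path VCF file (plain or bgzip/gzip).
#' @param field FORMAT field holding the comma-separated probability
#'   triplet (default `"GP"`).
#' @inheritParams stream_gen
#' @return List of [marker_record()] objects.
#' @export
read_vcf_gp <- function(path, field = "GP",
                        policy = c("strict", "lenient"), tol = 1e-3) {
  policy <- match.arg(policy)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gp <- vcfR::extract.gt(v, element = field)
  if (is.null(gp) || !ncol(gp))
    stop("no '", field, "' FORMAT entries found in '", path, "'")
  fix <- vcfR::getFIX(v)
  lapply(seq_len(nrow(gp)), function(m) {
    vals <- strsplit(unname(gp[m, ]), ",", fixed = TRUE)
    probs <- t(vapply(vals, function(x) {
      if (length(x) != 3L || anyNA(x) || any(x == "."))
        return(rep(NA_real_, 3L))
      suppressWarnings(as.numeric(x))
    }, numeric(3L)))
    n_absent <- sum(!stats::complete.cases(probs))
    probs[is.na(probs)] <- 0  # route absences through the missing policy
    norm <- normalize_dosages(probs, policy = policy, tol = tol,
                              snp_id = fix[m, "ID"])
    flags <- norm$flags
    if (n_absent > 0)
      flags <- unique(c(flags, FLAG_MISSING_EXCLUDED))
    marker_record(
      snp_id = if (is.na(fix[m, "ID"])) sprintf("%s:%s", fix[m, "CHROM"],
                                                fix[m, "POS"])
               else fix[m, "ID"],
      rs_id = if (is.na(fix[m, "ID"])) "." else fix[m, "ID"],
      chrom = fix[m, "CHROM"], position = as.integer(fix[m, "POS"]),
      allele_a = fix[m, "REF"], allele_b = fix[m, "ALT"],
      probs = norm$probs, flags = flags,
      n_missing = norm$n_missing, n_renormalized = norm$n_renormalized
    )
  })
}
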