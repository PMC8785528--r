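# GEN / SAMPLE parsing, the triplet-sum policy and metrics-table IO.

write_lines_tmp <- function(lines, ext = "") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("SAMPLE files parse, count individuals and reject malformed input", {
  path <- write_lines_tmp(c("ID_1 ID_2 missing", "0 0 0",
                            "ind1 ind1 0", "ind2 ind2 0", "ind3 ind3 0"))
  ss <- read_sample_file(path)
  expect_s3_class(ss, "sample_set")
  expect_equal(ss$n, 3L)
  expect_equal(ss$sample_ids, c("ind1", "ind2", "ind3"))

  empty <- write_lines_tmp(character())
  expect_error(read_sample_file(empty), "header")

  bad <- write_lines_tmp(c("ID_1 ID_2 missing", "x y z", "ind1 ind1 0"))
  expect_error(read_sample_file(bad), "type codes")

  headers_only <- write_lines_tmp(c("ID_1 ID_2 missing", "0 0 0"))
  expect_equal(read_sample_file(headers_only)$n, 0L)
})

test_that("GEN lines parse into marker records; malformed lines error with context", {
  path <- write_lines_tmp("snp1 rs1 100 A G 1 0 0 0 1 0")
  recs <- read_gen(path, expected_n = 2L, chrom = "7")
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$probs, triplets(1, 0, 0, 0, 1, 0))
  expect_equal(recs[[1]]$chrom, "7")
  expect_equal(recs[[1]]$position, 100L)

  # 7 trailing numbers: not a whole number of triplets
  bad_cols <- write_lines_tmp("snp1 rs1 100 A G 1 0 0 0 1 0 0.5")
  expect_error(read_gen(bad_cols, expected_n = 2L), "line 1")

  bad_num <- write_lines_tmp("snp1 rs1 100 A G 1 0 0 0 x 0")
  expect_error(read_gen(bad_num), "non-numeric")

  # a SAMPLE file with zero individuals makes any GEN line inconsistent
  expect_error(read_gen(path, expected_n = 0L), "expected 0")
})

test_that("6-column dialect with a leading chromosome label is auto-detected", {
  path <- write_lines_tmp(c("12 snp1 rs1 100 A G 1 0 0 0 1 0",
                            "12 snp2 rs2 200 C T 0 0 1 0 1 0"))
  recs <- read_gen(path)
  expect_equal(vapply(recs, `[[`, character(1), "chrom"), c("12", "12"))
  expect_equal(recs[[2]]$snp_id, "snp2")
  expect_equal(recs[[2]]$probs, triplets(0, 0, 1, 0, 1, 0))
})

test_that("triplet-sum policy: renormalize small deviations, missing and strict/lenient handling", {
  # sums 1.0005 (renormalizable), 0.5 (bad), 0 (missing), exact 1
  lines <- "snp1 rs1 100 A G 0.5005 0.5 0 0.25 0.25 0 0 0 0 1 0 0"
  path <- write_lines_tmp(lines)
  expect_error(read_gen(path, policy = "strict"), "individual 2")

  rec <- read_gen(path, policy = "lenient")[[1]]
  expect_setequal(rec$flags, c("RENORMALIZED", "MISSING_EXCLUDED"))
  expect_equal(sum(rec$probs[1, ]), 1, tolerance = 1e-12)
  expect_true(all(is.na(rec$probs[2, ])))  # bad sum excluded
  expect_true(all(is.na(rec$probs[3, ])))  # all-zero missing excluded
  expect_equal(rec$n_missing, 2L)
  expect_equal(rec$n_renormalized, 1L)
  expect_equal(compute_marker(rec)$n_used, 2L)
})

test_that("gzip round trip reproduces generated records exactly", {
  set.seed(11)
  cfg <- simulation_config(n_individuals = 7L, n_markers = 10L,
                           maf_law = maf_law_uniform(0.05, 0.5), seed = 11L)
  sim <- simulate_dataset(cfg)
  gz <- withr::local_tempfile(fileext = ".gen.gz")
  write_gen(sim$records, gz)
  back <- read_gen(gz, expected_n = 7L, chrom = "1")
  expect_length(back, 10L)
  for (m in seq_along(back)) {
    expect_identical(back[[m]]$snp_id, sim$records[[m]]$snp_id)
    expect_identical(back[[m]]$position, sim$records[[m]]$position)
    # bit-exact: no renormalization may touch generator triplets
    expect_identical(back[[m]]$probs, sim$records[[m]]$probs)
  }
})

test_that("streaming computation matches whole-file reading across chunk boundaries", {
  cfg <- simulation_config(n_individuals = 20L, n_markers = 13L, seed = 3L)
  sim <- simulate_dataset(cfg)
  path <- withr::local_tempfile(fileext = ".gen")
  write_gen(sim$records, path)
  whole <- compute_metrics(read_gen(path, chrom = "1"))
  streamed <- stream_gen(path, compute_marker, chrom = "1", chunk_size = 3L)
  streamed <- do.call(rbind, streamed)
  expect_equal(whole, streamed[order(streamed$position), ],
               ignore_attr = TRUE)
})

test_that("VCF genotype probabilities map onto marker records", {
  vcf <- write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype probabilities\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    paste("1\t500\trs10\tA\tG\t.\tPASS\t.\tGT:GP",
          "0/0:0.9,0.1,0", "0/1:0.2,0.7,0.1", "1/1:0,0,1", sep = "\t"),
    paste("1\t900\trs11\tA\tC\t.\tPASS\t.\tGT:GP",
          "0/0:1,0,0", "./.:.", "0/0:1,0,0", sep = "\t")
  ), ext = ".vcf")
  recs <- read_vcf_gp(vcf)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$probs,
               triplets(0.9, 0.1, 0, 0.2, 0.7, 0.1, 0, 0, 1))
  expect_equal(recs[[1]]$chrom, "1")
  expect_equal(recs[[1]]$position, 500L)
  # VCF order (hom-ref, het, hom-alt) with dose counting ALT
  expect_equal(compute_marker(recs[[1]])$maf_hat, (0.1 + 0.9 + 2) / 6)
  # missing GP entries are excluded, not fabricated
  expect_true(all(is.na(recs[[2]]$probs[2, ])))
  expect_match(paste(recs[[2]]$flags, collapse = ";"), "MISSING_EXCLUDED")
  expect_equal(compute_marker(recs[[2]])$n_used, 2L)
})

test_that("metrics table TSV round-trips including empty, flagged and NA rows", {
  empty <- make_metrics(numeric(), numeric())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_table(empty, path)
  expect_equal(nrow(read_metrics_table(path)), 0L)
  expect_equal(length(readLines(path)), 1L)  # header only

  one <- make_metrics(0.5, 0.9)
  one$flags <- "IAM_HWE_UNDEFINED"
  one$iam_hwe <- NA_real_
  write_metrics_table(one, path)
  back <- read_metrics_table(path)
  expect_equal(back$flags, "IAM_HWE_UNDEFINED")
  expect_true(is.na(back$iam_hwe))
  expect_equal(back$hiq, 0.9)

  set.seed(5)
  big <- make_metrics(runif(1000, -1, 1), runif(1000))
  big$maf_hat <- runif(1000)
  write_metrics_table(big, path)
  back <- read_metrics_table(path)
  expect_equal(nrow(back), 1000L)
  for (cl in c("maf_hat", "iam_hwe", "hiq"))
    expect_equal(signif(back[[cl]], 6), signif(big[[cl]], 6))
  expect_error(read_metrics_table(write_lines_tmp("a\tb\n1\t2")),
               "missing column")
})
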