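# EWMA smoothing and hot / very hot region calling.

test_that("EWMA recursion matches hand computation and fixed points", {
  expect_equal(ewma_smooth(c(1, 0, 0), alpha = 0.1), c(1, 0.9, 0.81))
  expect_equal(ewma_smooth(rep(0.4, 10), alpha = 0.1), rep(0.4, 10))
  x <- c(0.2, 0.9, 0.1, 0.5)
  expect_equal(ewma_smooth(x, alpha = 1), x)
  set.seed(3)
  y <- runif(200)
  expect_equal(ewma_smooth(y, 0.1), naive_ewma(y, 0.1), tolerance = 1e-12)
  expect_error(ewma_smooth(numeric()), "empty")
  expect_error(ewma_smooth(1:3, alpha = 0), "alpha")
})

test_that("undefined entries are transparent: state carried, NA emitted", {
  x <- c(1, NA, 0, NA, 0)
  s <- ewma_smooth(x, alpha = 0.1)
  expect_equal(s, c(1, NA, 0.9, NA, 0.81))
})

test_that("region calling covers exactly the sub-threshold runs", {
  trk <- data.frame(chrom = "2", position = c(10L, 20L, 30L, 40L, 50L),
                    smoothed = c(0.9, 0.9, 0.9, 0.9, 0.9))
  expect_equal(nrow(call_regions(trk, threshold = 0.5)), 0L)

  trk$smoothed <- c(0.9, 0.3, 0.9, 0.9, 0.9)
  reg <- call_regions(trk, threshold = 0.5, metric = "iam_hwe")
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start_bp, 20L)
  expect_equal(reg$end_bp, 20L)
  expect_equal(reg$n_variants, 1L)
  expect_equal(reg$severity, "hot")

  # strict comparison: a value exactly at the threshold is not hot
  trk$smoothed <- c(0.5, 0.5, 0.5, 0.5, 0.5)
  expect_equal(nrow(call_regions(trk, threshold = 0.5)), 0L)

  expect_error(call_regions(data.frame(chrom = "1", position = c(5L, 5L),
                                       smoothed = c(0, 0)), 0.5),
               "strictly increasing")
})

test_that("very hot regions are reported independently and may nest in hot ones", {
  trk <- data.frame(chrom = "1", position = (1:7) * 10L,
                    smoothed = c(0.9, 0.4, 0.1, 0.1, 0.4, 0.9, 0.9))
  reg <- call_regions(trk, threshold = 0.5, very_hot_factor = 0.5)
  hot <- reg[reg$severity == "hot", ]
  vh <- reg[reg$severity == "very_hot", ]
  expect_equal(c(hot$start_bp, hot$end_bp), c(20L, 50L))
  expect_equal(c(vh$start_bp, vh$end_bp), c(30L, 40L))
  expect_true(vh$start_bp >= hot$start_bp && vh$end_bp <= hot$end_bp)
})

test_that("every sub-threshold marker belongs to exactly one region (random tracks)", {
  set.seed(17)
  for (k in 1:10) {
    sm <- runif(100)
    trk <- data.frame(chrom = "3", position = cumsum(sample(1:50, 100, TRUE)),
                      smoothed = sm)
    reg <- call_regions(trk, threshold = 0.5)
    hot <- reg[reg$severity == "hot", ]
    runs <- naive_runs_below(sm, 0.5)
    expect_equal(nrow(hot), length(runs))
    for (i in seq_along(runs)) {
      expect_equal(hot$start_bp[i], trk$position[runs[[i]][1]])
      expect_equal(hot$end_bp[i], trk$position[runs[[i]][length(runs[[i]])]])
      expect_equal(hot$n_variants[i], length(runs[[i]]))
    }
    # disjoint and ordered within severity
    if (nrow(hot) > 1)
      expect_true(all(hot$start_bp[-1] > hot$end_bp[-nrow(hot)]))
  }
})

test_that("a planted low-accuracy span at the chromosome start is recovered exactly", {
  cfg <- simulation_config(
    n_individuals = 400L, n_markers = 120L,
    maf_law = maf_law_fixed(0.3), accuracy_lambda = 1,
    blur_mode = "hwe",
    hot_region_spec = list(start = 1L, n = 25L, lambda = 0),
    seed = 19L
  )
  sim <- simulate_dataset(cfg)
  met <- compute_metrics(sim$records)
  reg <- find_accuracy_regions(met, "iam_hwe", threshold = 0.05,
                               smoothing_factor = 0.1)
  hot <- reg[reg$severity == "hot", ]
  expect_equal(nrow(hot), 1L)
  expect_equal(hot$n_variants, 25L)
  expect_equal(hot$start_bp, met$position[1])
  expect_equal(hot$end_bp, met$position[25])
  # brute-force scan of the same smoothed track agrees
  trk <- attr(reg, "tracks")[["1"]]
  runs <- naive_runs_below(trk$smoothed, 0.05)
  expect_equal(length(runs), 1L)
  expect_equal(runs[[1]], 1:25)
})

test_that("smoothing restarts per chromosome", {
  met <- rbind(make_metrics(c(0, 0, 0), c(1, 1, 1), chrom = "1"),
               make_metrics(c(1, 1, 1), c(1, 1, 1), chrom = "2"))
  reg <- find_accuracy_regions(met, "iam_hwe", threshold = 0.5)
  hot <- reg[reg$severity == "hot", ]
  # chromosome 2 starts fresh at s1 = 1, so no carry-over region
  expect_equal(unique(hot$chrom), "1")
  expect_equal(hot$n_variants, 3L)
})

test_that("region summaries count sizes, singleton fraction and quantiles", {
  expect_equal(nrow(summarize_regions(empty <- data.frame(
    chrom = character(), start_bp = integer(), end_bp = integer(),
    n_variants = integer(), metric = character(), severity = character(),
    min_smoothed = numeric()))), 0L)

  reg <- data.frame(chrom = "1", start_bp = c(1L, 5L, 9L),
                    end_bp = c(1L, 5L, 30L), n_variants = c(1L, 1L, 21L),
                    metric = "iam_hwe", severity = "hot",
                    min_smoothed = 0.1)
  sm <- summarize_regions(reg)
  expect_equal(sm$n_regions, 3L)
  expect_equal(sm$fraction_singleton, 2 / 3)
  expect_equal(sm$size_max, 21L)

  set.seed(23)
  sizes <- sample(1:30, 100, TRUE)
  reg2 <- data.frame(chrom = "1", start_bp = 1L, end_bp = 2L,
                     n_variants = sizes,
                     metric = sample(c("iam_hwe", "hiq"), 100, TRUE),
                     severity = sample(c("hot", "very_hot"), 100, TRUE),
                     min_smoothed = 0)
  sm2 <- summarize_regions(reg2)
  expect_equal(sum(sm2$n_regions), 100L)
  expect_equal(sum(sm2$n_variants_total), sum(sizes))
  for (r in seq_len(nrow(sm2))) {
    sel <- reg2$metric == sm2$metric[r] & reg2$severity == sm2$severity[r]
    expect_equal(sm2$n_regions[r], sum(sel))
    expect_equal(sm2$fraction_singleton[r], mean(sizes[sel] == 1L))
  }
})

test_that("region files round out in both coordinate conventions", {
  reg <- data.frame(chrom = "7", start_bp = 100L, end_bp = 250L,
                    n_variants = 5L, metric = "hiq", severity = "hot",
                    min_smoothed = 0.3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_regions(reg, tsv)
  lines <- readLines(tsv)
  expect_match(lines[1], "1-based")
  body <- utils::read.table(tsv, header = TRUE, sep = "\t",
                            comment.char = "#")
  expect_equal(body$start_bp, 100L)

  bed <- withr::local_tempfile(fileext = ".bed")
  write_regions(reg, bed, bed = TRUE)
  bl <- utils::read.table(bed, sep = "\t")
  expect_equal(bl$V2, 99L)   # 0-based half-open
  expect_equal(bl$V3, 250L)
})
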