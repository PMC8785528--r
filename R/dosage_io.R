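# IO for Oxford GEN / SAMPLE dosage files and the per-marker metrics table.
#
# GEN dialects: the classic 5 identity columns (snp_id rs_id position
# alleleA alleleB) followed by 3N probabilities, or a 6-column dialect with
# the chromosome label first. Files may be gzip-compressed. Positions are
# 1-based point coordinates.

# flag vocabulary shared across modules
FLAG_RENORMALIZED <- "RENORMALIZED"
FLAG_MISSING_EXCLUDED <- "MISSING_EXCLUDED"
FLAG_IAM_HWE_UNDEFINED <- "IAM_HWE_UNDEFINED"

METRICS_COLUMNS <- c(
  "snp_id", "rs_id", "chrom", "position",
  "maf_hat", "q_bar", "iam_chance", "iam_hwe", "hiq",
  "n_used", "flags"
)

#' Construct a marker dosage record
#'
#' A marker record holds one marker's identity plus the N x 3 matrix of
#' a-posteriori genotype probability triplets (p0, p1, p2), one row per
#' individual. Rows excluded by the reader (missing or unparseable
#' individuals) are `NA`.
#'
#' @param snp_id,rs_id Marker identifiers.
#' @param chrom Chromosome label (autosome expected); may be `NA`.
#' @param position 1-based base-pair position (integer >= 1).
#' @param allele_a,allele_b Allele codes; dose counts allele B.
#' @param probs Numeric N x 3 matrix of genotype probabilities in \[0, 1\].
#' @param flags Character vector of per-marker flags.
#' @param n_missing Count of individuals excluded as missing/invalid.
#' @param n_renormalized Count of triplets renormalized to sum 1.
#' @return An object of class `marker_record`.
#' @export
marker_record <- function(snp_id, rs_id, chrom, position, allele_a, allele_b,
                          probs, flags = character(), n_missing = 0L,
                          n_renormalized = 0L) {
  if (!is.matrix(probs) || ncol(probs) != 3L || nrow(probs) < 1L)
    stop("'probs' must be an N x 3 matrix with N >= 1")
  position <- as.integer(position)
  if (is.na(position) || position < 1L)
    stop("marker '", snp_id, "': position must be an integer >= 1")
  ok <- !is.na(probs)
  if (any(probs[ok] < 0 | probs[ok] > 1))
    stop("marker '", snp_id, "': probabilities must lie in [0, 1]")
  structure(
    list(snp_id = as.character(snp_id), rs_id = as.character(rs_id),
         chrom = as.character(chrom), position = position,
         allele_a = as.character(allele_a), allele_b = as.character(allele_b),
         probs = probs, flags = flags,
         n_missing = as.integer(n_missing),
         n_renormalized = as.integer(n_renormalized)),
    class = "marker_record"
  )
}

#' @export
print.marker_record <- function(x, ...) {
  cat("<marker_record> ", x$snp_id, " (", x$rs_id, ") ",
      x$chrom, ":", x$position, "  ", nrow(x$probs), " individuals",
      if (length(x$flags)) paste0("  [", paste(x$flags, collapse = ","), "]"),
      "\n", sep = "")
  invisible(x)
}

#' Read an Oxford SAMPLE file
#'
#' The SAMPLE format carries two header lines (column names and column type
#' codes) followed by one line per individual.
#'
#' @param path Path to the SAMPLE file.
#' @return An object of class `sample_set`: a list with `sample_ids`
#'   (ordered IDs, first column) and `n`.
#' @export
read_sample_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("malformed SAMPLE file '", path,
         "': expected two header lines, found ", length(lines), " line(s)")
  hdr1 <- strsplit(trimws(lines[[1L]]), "[ \t]+")[[1L]]
  hdr2 <- strsplit(trimws(lines[[2L]]), "[ \t]+")[[1L]]
  if (length(hdr1) < 2L)
    stop("malformed SAMPLE file '", path,
         "': header line 1 must name at least two identifier columns")
  if (length(hdr2) != length(hdr1) || hdr2[[1L]] != "0")
    stop("malformed SAMPLE file '", path,
         "': header line 2 must carry column type codes starting with '0'")
  body <- lines[-(1:2)]
  ids <- if (length(body))
    vapply(strsplit(trimws(body), "[ \t]+"), `[[`, character(1L), 1L)
  else character()
  structure(list(sample_ids = ids, n = length(ids)), class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> ", x$n, " individuals\n", sep = "")
  invisible(x)
}

is_chrom_label <- function(x) {
  grepl("^(chr)?([0-9]{1,2}|X|Y|MT?)$", x, ignore.case = TRUE)
}

# Decide once per file whether lines carry 5 or 6 identity columns.
detect_gen_dialect <- function(toks, path, lineno) {
  n <- length(toks)
  if (n > 5L && (n - 5L) %% 3L == 0L) return(5L)
  if (n > 6L && (n - 6L) %% 3L == 0L && is_chrom_label(toks[[1L]])) return(6L)
  stop("format error in '", path, "' line ", lineno, ": ", n,
       " columns cannot be split into 5 (or 6) identity columns plus ",
       "3 probabilities per individual")
}

# Apply the triplet-sum policy to one marker's probability matrix.
#  - all-zero triplet: missing individual, excluded (row set to NA)
#  - |sum - 1| <= 1e-9: left untouched (numerically already normalized)
#  - 1e-9 < |sum - 1| <= tol: renormalized to sum exactly 1
#  - |sum - 1| > tol or value outside [0,1]: error (strict) or excluded
#    (lenient)
normalize_dosages <- function(probs, policy = c("strict", "lenient"),
                              tol = 1e-3, snp_id = "?", lineno = NA) {
  policy <- match.arg(policy)
  rs <- rowSums(probs)
  missing <- rs == 0
  bad_value <- apply(probs < 0 | probs > 1, 1L, any)
  dev <- abs(rs - 1)
  bad <- !missing & (dev > tol | bad_value)
  if (any(bad) && policy == "strict") {
    i <- which(bad)[[1L]]
    stop("validation error: marker '", snp_id, "'",
         if (!is.na(lineno)) paste0(" (line ", lineno, ")"),
         ", individual ", i, ": triplet (",
         paste(signif(probs[i, ], 6), collapse = ", "),
         ") violates the dosage-sum policy (sum = ", signif(rs[[i]], 6), ")")
  }
  renorm <- !missing & !bad & dev > 1e-9
  if (any(renorm))
    probs[renorm, ] <- probs[renorm, , drop = FALSE] / rs[renorm]
  probs[missing | bad, ] <- NA_real_
  flags <- character()
  if (any(renorm)) flags <- c(flags, FLAG_RENORMALIZED)
  if (any(missing | bad)) flags <- c(flags, FLAG_MISSING_EXCLUDED)
  list(probs = probs, flags = flags,
       n_missing = sum(missing | bad), n_renormalized = sum(renorm))
}

parse_gen_tokens <- function(toks, dialect, chrom, path, lineno,
                             expected_n, policy, tol) {
  off <- if (dialect == 6L) 1L else 0L
  n_tok <- length(toks)
  if (n_tok <= 5L + off || (n_tok - 5L - off) %% 3L != 0L)
    stop("format error in '", path, "' line ", lineno, ": ", n_tok,
         " columns do not give whole probability triplets after ",
         5L + off, " identity columns")
  n_ind <- (n_tok - 5L - off) %/% 3L
  if (!is.null(expected_n) && n_ind != expected_n)
    stop("format error in '", path, "' line ", lineno, ": ", n_ind,
         " individuals on this line, expected ", expected_n)
  pv <- suppressWarnings(as.numeric(toks[(6L + off):n_tok]))
  if (anyNA(pv)) {
    j <- which(is.na(pv))[[1L]]
    stop("format error in '", path, "' line ", lineno,
         ": non-numeric probability '", toks[[5L + off + j]], "'")
  }
  pos <- suppressWarnings(as.integer(toks[[3L + off]]))
  if (is.na(pos))
    stop("format error in '", path, "' line ", lineno,
         ": non-integer position '", toks[[3L + off]], "'")
  probs <- matrix(pv, ncol = 3L, byrow = TRUE)
  snp_id <- toks[[1L + off]]
  norm <- normalize_dosages(probs, policy = policy, tol = tol,
                            snp_id = snp_id, lineno = lineno)
  marker_record(
    snp_id = snp_id, rs_id = toks[[2L + off]],
    chrom = if (dialect == 6L) toks[[1L]] else chrom,
    position = pos,
    allele_a = toks[[4L + off]], allele_b = toks[[5L + off]],
    probs = norm$probs, flags = norm$flags,
    n_missing = norm$n_missing, n_renormalized = norm$n_renormalized
  )
}

#' Stream markers from a GEN dosage file
#'
#' Reads a (possibly gzip-compressed) GEN file line by line and applies
#' `fun` to each [marker_record()] as it is parsed, so that only one chunk
#' of lines is ever held in memory. The number of individuals must be
#' constant across the file; the first line fixes it when `expected_n` is
#' not given.
#'
#' @param path GEN file path (`.gz` accepted).
#' @param fun Function applied to each record; its results are collected in
#'   a list. Defaults to `identity`.
#' @param expected_n Expected number of individuals per line (e.g. from
#'   [read_sample_file()]); checked against every line.
#' @param chrom Chromosome label applied to all records (GEN files are
#'   conventionally per-chromosome); ignored for the 6-column dialect,
#'   which carries its own label.
#' @param policy `"strict"` (default) errors on triplets whose sum deviates
#'   from 1 by more than `tol`; `"lenient"` excludes the individual and
#'   flags the marker.
#' @param tol Triplet-sum tolerance for renormalization (default `1e-3`).
#' @param chunk_size Lines read per chunk.
#' @return List of `fun` results, one per marker line.
#' @export
stream_gen <- function(path, fun = identity, expected_n = NULL,
                       chrom = NA_character_,
                       policy = c("strict", "lenient"), tol = 1e-3,
                       chunk_size = 500L) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("cannot open GEN file '", path, "'")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  out <- vector("list", 0L)
  lineno <- 0L
  dialect <- NULL
  n_ref <- expected_n
  repeat {
    lines <- readLines(con, n = chunk_size, warn = FALSE)
    if (!length(lines)) break
    for (ln in lines) {
      lineno <- lineno + 1L
      if (!nzchar(trimws(ln))) next
      toks <- strsplit(trimws(ln), "[ \t]+")[[1L]]
      if (is.null(dialect)) dialect <- detect_gen_dialect(toks, path, lineno)
      rec <- parse_gen_tokens(toks, dialect, chrom, path, lineno,
                              n_ref, policy, tol)
      if (is.null(n_ref)) n_ref <- nrow(rec$probs)
      out[[length(out) + 1L]] <- fun(rec)
    }
  }
  out
}

#' Read a GEN dosage file into marker records
#'
#' Convenience wrapper over [stream_gen()] that materializes all records.
#' For large files prefer [compute_gen_metrics()], which streams.
#'
#' @inheritParams stream_gen
#' @return List of [marker_record()] objects.
#' @export
read_gen <- function(path, expected_n = NULL, chrom = NA_character_,
                     policy = c("strict", "lenient"), tol = 1e-3) {
  stream_gen(path, identity, expected_n = expected_n, chrom = chrom,
             policy = match.arg(policy), tol = tol)
}

# numeric ordering of chromosome labels where possible ("10" after "9")
chrom_rank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  num <- suppressWarnings(as.numeric(x))
  num[is.na(num)] <- 100 + as.numeric(factor(x[is.na(num)]))
  num
}

sort_metrics <- function(metrics) {
  metrics[order(chrom_rank(metrics$chrom), metrics$position), ,
          drop = FALSE]
}

#' Write / read the per-marker metrics table
#'
#' Tab-separated with a fixed header; numeric columns carry at least 10
#' significant digits so a write/read round trip is faithful well beyond 6
#' significant digits. Empty flag sets are written as `"."`.
#'
#' @param metrics Metrics data frame as produced by [compute_metrics()].
#' @param path Output path.
#' @return `write_metrics_table()` returns `path` invisibly;
#'   `read_metrics_table()` returns the metrics data frame.
#' @export
write_metrics_table <- function(metrics, path) {
  missing_cols <- setdiff(METRICS_COLUMNS, names(metrics))
  if (length(missing_cols))
    stop("metrics table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- metrics[, METRICS_COLUMNS, drop = FALSE]
  for (cl in c("maf_hat", "q_bar", "iam_chance", "iam_hwe", "hiq"))
    df[[cl]] <- ifelse(is.na(df[[cl]]), "NA",
                       formatC(df[[cl]], digits = 12, format = "g"))
  df$flags[!nzchar(df$flags) | is.na(df$flags)] <- "."
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(METRICS_COLUMNS, header)
  if (length(missing_cols))
    stop("format error reading '", path, "': missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df <- utils::read.table(
    path, header = TRUE, sep = "\t", quote = "", comment.char = "",
    stringsAsFactors = FALSE,
    colClasses = c(snp_id = "character", rs_id = "character",
                   chrom = "character", flags = "character")
  )
  df$flags[df$flags == "."] <- ""
  for (cl in c("maf_hat", "q_bar", "iam_chance", "iam_hwe", "hiq"))
    df[[cl]] <- as.numeric(df[[cl]])
  df$position <- as.integer(df$position)
  df$n_used <- as.integer(df$n_used)
  df
}
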