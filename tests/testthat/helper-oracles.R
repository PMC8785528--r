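# Independent oracles and fixture builders used across the suite.
# All oracles are deliberately naive (explicit loops, no shared code with
# the package internals).

triplets <- function(...) matrix(c(...), ncol = 3, byrow = TRUE)

# loop-based reference computation of every per-marker quantity
naive_marker_metrics <- function(probs) {
  keep <- apply(probs, 1L, function(r) !any(is.na(r)))
  P <- probs[keep, , drop = FALSE]
  n <- nrow(P)
  d <- numeric(n)
  Q <- numeric(n)
  for (i in seq_len(n)) {
    d[i] <- 0 * P[i, 1] + 1 * P[i, 2] + 2 * P[i, 3]
    Q[i] <- sum(P[i, ] * (1 - P[i, ]))
  }
  f <- sum(d) / (2 * n)
  qbar <- mean(Q)
  qh <- (-2 * f) * (f - 1) * (3 * f^2 - 3 * f + 2)
  f_ad <- c(mean(P[, 1]), mean(P[, 2]), mean(P[, 3]))
  bg <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    mx <- which(P[i, ] == max(P[i, ]))
    bg[i, mx] <- 1 / length(mx)
  }
  f_bg <- colMeans(bg)
  bc <- min(sum(sqrt(f_ad * f_bg)), 1)
  list(maf_hat = f, q_bar = qbar,
       iam_chance = 1 - qbar / (2 / 3),
       iam_hwe = if (qh > 0) 1 - qbar / qh else NA_real_,
       hiq = 1 - sqrt(1 - bc), n_used = n)
}

# random normalized triplet matrix mixing crisp and fuzzy rows
random_probs <- function(n, crisp_frac = 0.3) {
  P <- matrix(stats::runif(n * 3), n, 3)
  P <- P / rowSums(P)
  crisp <- stats::runif(n) < crisp_frac
  for (i in which(crisp)) {
    g <- sample.int(3L, 1L)
    P[i, ] <- 0
    P[i, g] <- 1
  }
  P
}

# loop-based EWMA reference
naive_ewma <- function(x, alpha) {
  s <- numeric(length(x))
  s[1] <- x[1]
  for (t in seq_along(x)[-1]) s[t] <- alpha * x[t] + (1 - alpha) * s[t - 1]
  s
}

# brute-force scan: indices of maximal runs with value < cutoff
naive_runs_below <- function(values, cutoff) {
  below <- !is.na(values) & values < cutoff
  out <- list()
  i <- 1L
  while (i <= length(below)) {
    if (below[i]) {
      j <- i
      while (j < length(below) && below[j + 1L]) j <- j + 1L
      out[[length(out) + 1L]] <- i:j
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# minimal well-formed metrics data frame for threshold/region tests
make_metrics <- function(iam, hiq, maf = 0.3, chrom = "1",
                         position = seq_along(iam) * 1000L) {
  n <- length(iam)
  data.frame(
    snp_id = sprintf("snp%d", seq_len(n)),
    rs_id = sprintf("rs%d", seq_len(n)),
    chrom = rep_len(as.character(chrom), n),
    position = as.integer(position),
    maf_hat = rep_len(maf, n), q_bar = rep_len(0.1, n),
    iam_chance = rep_len(0.5, n),
    iam_hwe = iam, hiq = hiq, n_used = rep_len(100L, n),
    flags = rep_len("", n),
    stringsAsFactors = FALSE
  )
}

# exact bivariate normal sampler with known location/covariance
rbivnorm <- function(n, mu, sigma) {
  z <- matrix(stats::rnorm(2 * n), n, 2)
  sweep(z %*% chol(sigma), 2L, mu, `+`)
}
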