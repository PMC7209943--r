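# Independent oracles, deliberately written along different routes than
# the package implementation.

# Direct-summation CvM oracle: evaluate both ECDFs with stats::ecdf at
# every pooled observation and sum the squared differences.
oracle_cvm <- function(a, b) {
  pooled <- c(a, b)
  fa <- stats::ecdf(a)
  fb <- stats::ecdf(b)
  na <- length(a); nb <- length(b); n <- na + nb
  na * nb / n^2 * sum((fa(pooled) - fb(pooled))^2)
}

# Exhaustive permutation oracle: exact upper-tail probability of the CvM
# statistic over all choose(N, n_a) label assignments.
oracle_perm_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  obs <- oracle_cvm(a, b)
  idx <- utils::combn(length(pooled), na)
  stats <- apply(idx, 2, function(i) oracle_cvm(pooled[i], pooled[-i]))
  mean(stats >= obs - 1e-12)
}

# Hand-written Benjamini-Hochberg step-up: sort ascending, take running
# minima of p * m / rank from the largest rank down, cap at 1, unsort.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exact binomial upper tail by coefficient summation.
oracle_binom_tail <- function(k, n) {
  sum(choose(n, k:n)) / 2^n
}

# Direct-tally prevalence oracle: percentage of informative answers other
# than "never" for one question column.
oracle_percent_engaging <- function(codes) {
  inf <- codes[codes >= 1 & codes <= 4]
  100 - round_half_up(100 * sum(inf == 1) / length(inf), 2)
}

# Evaluate `code` under a fixed seed (tests only).
with_seed_for_tests <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# Build a small raw survey CSV on disk and return its path.
write_raw_survey_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "id,age,sex,country,q1,q2,q3"
  writeLines(c(header, rows), path)
  path
}
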