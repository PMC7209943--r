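# Two-sample Cramer-von Mises statistic on ordinal ratings, permutation
# null, and multiple-testing correction.  This is the inferential core of
# the package.

#' Two-sample Cramer-von Mises statistic
#'
#' Computes the tie-aware two-sample Cramer-von Mises criterion between two
#' samples of ordinal ratings (or any numeric values).  Both empirical
#' cumulative distribution functions are evaluated at every pooled value and
#' the squared differences are summed with pooled-count weights.  The
#' default `"anderson"` normalization is the classical two-sample form
#'
#' \deqn{T = \frac{n_a n_b}{N^2} \sum_{x \in pooled} (F_a(x) - F_b(x))^2,}
#'
#' where the sum runs over all \eqn{N = n_a + n_b} pooled observations
#' (equivalently over the distinct values weighted by their pooled counts).
#' `"pooled_sum"` drops the \eqn{n_a n_b / N^2} factor; the variant is
#' pluggable because published CvM values do not always state their
#' normalization.
#'
#' The statistic is symmetric in its arguments, invariant under any
#' strictly monotone recoding of the categories, and zero iff the two
#' ECDFs coincide at every pooled value.
#'
#' @param a,b numeric vectors of ratings (for questionnaire work, codes
#'   1-4; uninformative answers must be removed first).
#' @param variant normalization, `"anderson"` (default) or `"pooled_sum"`.
#' @return the statistic (a non-negative scalar).
#' @examples
#' cvm_statistic(c(1, 2, 3, 4), c(1, 2, 3, 4))  # 0
#' cvm_statistic(c(1, 1, 2), c(3, 4, 4))
#' @export
cvm_statistic <- function(a, b, variant = c("anderson", "pooled_sum")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("samples must be finite")
  vals <- sort(unique(c(a, b)))
  ca <- tabulate(match(a, vals), nbins = length(vals))
  cb <- tabulate(match(b, vals), nbins = length(vals))
  cvm_from_counts(ca, cb, variant)
}

# Statistic from per-value counts of the two groups (vectors over the
# pooled support).  Shared by the observed statistic and the permutation
# machinery.
cvm_from_counts <- function(ca, cb, variant = "anderson") {
  na <- sum(ca); nb <- sum(cb); n <- na + nb
  fa <- cumsum(ca) / na
  fb <- cumsum(cb) / nb
  s <- sum((ca + cb) * (fa - fb)^2)
  if (variant == "anderson") s <- s * na * nb / n^2
  s
}

#' Permutation test for the two-sample CvM statistic
#'
#' Estimates the p-value of [cvm_statistic()] by re-assigning the group
#' labels to the pooled ratings at random `n_perm` times and recomputing
#' the statistic for each assignment.  For categorical data the permuted
#' statistic depends only on the 2-by-K contingency table of the permuted
#' labels, whose null distribution is multivariate hypergeometric with the
#' pooled category counts as margins; the implementation therefore samples
#' tables directly (sequential [stats::rhyper()]), which is exact and
#' vectorizes to millions of permutations.
#'
#' The p-value uses the add-one estimator
#' \deqn{p = (1 + \#\{T^{perm} \ge T^{obs}\}) / (n_{perm} + 1),}
#' counting the observed assignment among the permutations, so `p_boot` is
#' always in `(0, 1]` and ties count as extreme (conservative).
#'
#' @param a,b numeric rating vectors (see [cvm_statistic()]).
#' @param n_perm number of random label assignments (default 10000; use
#'   1e6 to match high-precision published p-values).
#' @param seed integer seed for the permutation stream; the caller's RNG
#'   state is left untouched.  Identical seed, identical p-value.
#' @param variant passed to [cvm_statistic()].
#' @return an object of class `cvm_test`: a list with `statistic`,
#'   `p_boot`, `p_fdr` (`NA` until a family correction is applied), `n_a`,
#'   `n_b`, `n_perm`, `seed`, `variant`.
#' @examples
#' r <- permutation_test(c(1, 1, 2, 2), c(3, 3, 4, 4), n_perm = 999, seed = 1)
#' r$p_boot
#' @export
permutation_test <- function(a, b, n_perm = 10000, seed = NULL,
                             variant = c("anderson", "pooled_sum")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  if (length(a) + length(b) < 2) stop("need at least 2 pooled observations")

  vals <- sort(unique(c(a, b)))
  if (length(vals) == 1) {
    warning("all pooled ratings identical; statistic 0, p = 1", call. = FALSE)
    return(new_cvm_test(0, 1, length(a), length(b), n_perm, seed, variant))
  }
  ca <- tabulate(match(a, vals), nbins = length(vals))
  cb <- tabulate(match(b, vals), nbins = length(vals))
  obs <- cvm_from_counts(ca, cb, variant)

  perm <- with_seed(seed, perm_cvm_stats(ca + cb, sum(ca), n_perm, variant))
  p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  new_cvm_test(obs, p, length(a), length(b), n_perm, seed, variant)
}

# n_perm draws of the CvM statistic under random label assignment, given
# the pooled per-category counts `ct` and group-A size `na`.  Group-A
# category counts are a multivariate hypergeometric draw, sampled
# category by category with rhyper (vectorized across permutations).
perm_cvm_stats <- function(ct, na, n_perm, variant = "anderson") {
  k <- length(ct)
  n <- sum(ct)
  nb <- n - na
  A <- matrix(0, nrow = n_perm, ncol = k)
  left_a <- rep(na, n_perm)       # group-A slots still to fill
  left_n <- n                     # pooled observations still unassigned
  for (j in seq_len(k - 1)) {
    A[, j] <- stats::rhyper(n_perm, m = ct[j], n = left_n - ct[j], k = left_a)
    left_a <- left_a - A[, j]
    left_n <- left_n - ct[j]
  }
  A[, k] <- left_a

  cumA <- A
  for (j in seq_len(k - 1) + 1) cumA[, j] <- cumA[, j - 1] + A[, j]
  cumT <- cumsum(ct)
  fa <- cumA / na
  fb <- (matrix(cumT, n_perm, k, byrow = TRUE) - cumA) / nb
  s <- as.vector((fa - fb)^2 %*% ct)
  if (variant == "anderson") s <- s * na * nb / n^2
  s
}

new_cvm_test <- function(statistic, p_boot, n_a, n_b, n_perm, seed, variant) {
  structure(list(statistic = statistic, p_boot = p_boot, p_fdr = NA_real_,
                 n_a = n_a, n_b = n_b, n_perm = n_perm,
                 seed = if (is.null(seed)) NA_integer_ else seed,
                 variant = variant),
            class = "cvm_test")
}

#' @export
print.cvm_test <- function(x, ...) {
  cat(sprintf("Two-sample CvM permutation test (%s variant)\n", x$variant))
  cat(sprintf("  n_a = %d, n_b = %d, n_perm = %d\n", x$n_a, x$n_b, x$n_perm))
  cat(sprintf("  CvM = %.4g, bootstrap p = %.4g", x$statistic, x$p_boot))
  if (!is.na(x$p_fdr)) cat(sprintf(", corrected p = %.4g", x$p_fdr))
  cat("\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values for a declared family of tests: with the
#' p-values sorted ascending, the i-th adjusted value is
#' \eqn{\min_{j \ge i} (p_{(j)} m / j)} capped at 1, returned in the input
#' order.  Delegates to [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.0002, 0.025, rep(0.5, 8)))[1:2]  # 0.002, 0.125
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1] with no NA")
  }
  stats::p.adjust(p, method = "BH")
}

#' Exact binomial direction probability
#'
#' Upper-tail probability \eqn{P(X \ge k)} for \eqn{X \sim Binomial(n, 1/2)}:
#' the chance that at least `k` of `n` subjects move in a given direction
#' when each direction is equally likely.  Used to test whether the count
#' of subjects increasing (e.g. nasal airflow during hand-at-face epochs)
#' exceeds chance.
#'
#' @param k_increase number of subjects moving in the tested direction.
#' @param n number of subjects.
#' @return the exact tail probability.
#' @examples
#' binomial_direction_test(12, 17)  # 9402/131072 = 0.0717...
#' @export
binomial_direction_test <- function(k_increase, n) {
  if (n < 1 || k_increase < 0 || k_increase > n) {
    stop("need 0 <= k_increase <= n and n >= 1")
  }
  stats::pbinom(k_increase - 1, size = n, prob = 0.5, lower.tail = FALSE)
}
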