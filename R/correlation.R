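#' Permutation null distribution for absolute Pearson correlation
#'
#' Builds the reference null used to turn an absolute Pearson correlation
#' into a correlation *probability* (its empirical percentile under the
#' null of no association). The null is obtained from `B` sample-label
#' permutations of a seeded reference pair of patterns of length
#' `n_samples`; under exchangeability the permutation distribution of `r`
#' depends on the patterns only through the sample size, so one null per
#' sample size serves every gene pair, keeping the whole pipeline at a
#' single permutation pass.
#'
#' @param n_samples Number of samples the correlations are computed over.
#' @param B Number of label permutations (default 1000).
#' @param seed Integer seed; the null is a pure function of
#'   `(n_samples, B, seed)`.
#' @return Object of class `corr_null` holding the sorted null |r| values.
#' @seealso [correlation_probability()]
#' @export
corr_null <- function(n_samples, B = 1000L, seed = 1L) {
  if (n_samples < 3) stop("correlation null needs >= 3 samples")
  set.seed(as.integer(seed))
  x <- zscore(stats::rnorm(n_samples))
  y <- stats::rnorm(n_samples)
  q <- vapply(seq_len(B), function(b) abs(stats::cor(x, sample(y))),
              numeric(1))
  structure(list(n = as.integer(n_samples), B = as.integer(B),
                 seed = as.integer(seed), q = sort(q)),
            class = "corr_null")
}

#' @export
print.corr_null <- function(x, ...) {
  cat(sprintf("<corr_null> n = %d, B = %d, seed = %d, q95(|r|) = %.3f\n",
              x$n, x$B, x$seed, stats::quantile(x$q, 0.95)))
  invisible(x)
}

# Empirical percentile of |r| within a corr_null (vectorized, monotone).
# Beyond the largest null value the percentile is continued linearly up to
# |r| = 1 so it keeps increasing instead of plateauing at 1; it reaches
# exactly 1 only at |r| = 1.
percentile_from_r <- function(rabs, null) {
  r <- pmin(rabs, 1)
  B <- null$B
  qmax <- null$q[B]
  p <- findInterval(r, null$q) / B
  hi <- r >= qmax & qmax < 1
  if (any(hi)) {
    p[hi] <- (B - 1) / B + (r[hi] - qmax) / (1 - qmax) / B
  }
  p
}

# Correlation probability: the absolute correlation damped by its
# permutation percentile, P = percentile(|r|) * |r|.  The percentile acts
# as the probability that the correlation is genuine rather than a
# finite-sample fluctuation; multiplying by |r| keeps the full dynamic
# range at large correlations, which the discounted module-search rewards
# require (a rank percentile alone saturates at 1 for every correlation
# beyond the null's support, flattening the value function).
prob_from_r <- function(rabs, null) {
  percentile_from_r(rabs, null) * pmin(rabs, 1)
}

#' Correlation probability between two expression patterns
#'
#' Returns `|Pearson r(x, y)|` damped by its empirical percentile within a
#' null distribution of `|r|` built from sample-label permutations:
#' `P = percentile(|r|) * |r|`. Correlations indistinguishable from the
#' permutation null are shrunk towards 0 while strong correlations keep
#' their magnitude, so `P` is a null-calibrated correlation strength in
#' \[0, 1\]: strictly monotone in `|r|`, exactly 1 only for perfect
#' (anti-)correlation, near 0 for independent patterns, and invariant to
#' sign flips and affine rescaling of either pattern.
#'
#' @param x,y Numeric patterns of equal length >= 3, non-constant.
#' @param null Optional precomputed [corr_null()] for `length(x)` samples;
#'   when `NULL` the null is built by permuting `y` itself `B` times.
#' @param B,seed Permutation count and seed used when `null` is `NULL`.
#' @return Scalar in \[0, 1\].
#' @export
#' @examples
#' x <- rnorm(30)
#' correlation_probability(x, x)          # 1: |r| = 1 dominates any null
#' correlation_probability(x, -x)         # 1: sign-invariant by design
correlation_probability <- function(x, y, null = NULL, B = 1000L, seed = 1L) {
  if (length(x) != length(y)) stop("patterns must have equal length")
  if (length(x) < 3) stop("patterns must have length >= 3")
  if (popsd(x) < 1e-12 || popsd(y) < 1e-12) stop("zero variance pattern")
  robs <- abs(stats::cor(x, y))
  if (is.null(null)) {
    set.seed(as.integer(seed))
    q <- sort(vapply(seq_len(B), function(b) abs(stats::cor(x, sample(y))),
                     numeric(1)))
    null <- structure(list(n = length(x), B = as.integer(B), q = q),
                      class = "corr_null")
    return(prob_from_r(robs, null))
  }
  if (!inherits(null, "corr_null")) stop("null must be a corr_null object")
  if (null$n != length(x)) {
    stop("corr_null built for n = ", null$n, " but patterns have length ",
         length(x))
  }
  prob_from_r(robs, null)
}
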