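## Nonparametric two-sample and paired tests used throughout: two-sided
## Wilcoxon-Mann-Whitney rank-sum and Wilcoxon signed-rank, with exact
## small-sample enumeration where it is feasible and tie-free, and the
## tie-corrected normal approximation otherwise.

#' Two-sided Mann-Whitney / Wilcoxon rank-sum p-value
#'
#' Exact enumeration when \code{min(n, m) <= 8} and the pooled sample is
#' tie-free; tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param x,y numeric samples (non-empty).
#' @return two-sided p-value in [0, 1].
#' @export
rankSumTest <- function(x, y) {
  if (!length(x) || !length(y)) stopTyped("validationError", "empty sample")
  exact <- min(length(x), length(y)) <= 8L && !anyDuplicated(c(x, y))
  stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                     correct = TRUE)$p.value
}

#' Two-sided Wilcoxon signed-rank p-value for paired samples
#'
#' @param x numeric sample, or paired differences if \code{y} is NULL.
#' @param y optional second paired sample (same length as \code{x}).
#' @return two-sided p-value in [0, 1].
#' @export
signedRankTest <- function(x, y = NULL) {
  if (!length(x)) stopTyped("validationError", "empty sample")
  d <- if (is.null(y)) x else {
    if (length(x) != length(y))
      stopTyped("validationError", "paired samples must have equal length")
    x - y
  }
  if (all(d == 0)) return(1)  # no signal in any pair
  exact <- length(d) <= 25L && !anyDuplicated(abs(d)) && all(d != 0)
  stats::wilcox.test(d, alternative = "two.sided", exact = exact,
                     correct = TRUE)$p.value
}

#' Compare two groups with the appropriate Wilcoxon test
#'
#' Unpaired groups use the two-sided Wilcoxon-Mann-Whitney rank-sum test,
#' paired groups the two-sided Wilcoxon signed-rank test.
#'
#' @param a,b numeric samples; for \code{paired = TRUE} they must be equal
#'   length and aligned.
#' @param paired logical.
#' @return list with \code{test}, \code{p_value}, \code{n1}, \code{n2},
#'   \code{median1}, \code{median2}.
#' @export
compareGroups <- function(a, b, paired = FALSE) {
  p <- if (paired) signedRankTest(a, b) else rankSumTest(a, b)
  list(test = if (paired) "signed_rank_paired" else "ranksum_unpaired",
       p_value = p, n1 = length(a), n2 = length(b),
       median1 = stats::median(a), median2 = stats::median(b))
}

## Vectorized two-sided rank-sum p-values for many small tests at once:
## rows of `post` vs rows of `pre` (K x nPost, K x nPre). Tie-corrected
## normal approximation with continuity correction, matching
## wilcox.test(exact = FALSE, correct = TRUE). Rows where every pooled value
## is identical get p = 1.
rankSumPMatrix <- function(post, pre) {
  K <- nrow(post); n <- ncol(post); m <- ncol(pre)
  X <- cbind(post, pre)
  Nt <- n + m
  p <- numeric(K)
  for (k in seq_len(K)) {
    r <- rank(X[k, ])
    W <- sum(r[seq_len(n)]) - n * (n + 1) / 2
    tieTerm <- if (anyDuplicated(X[k, ])) {
      tie <- table(X[k, ])
      sum(tie^3 - tie) / (Nt * (Nt - 1))
    } else 0
    sig2 <- (n * m / 12) * ((Nt + 1) - tieTerm)
    if (sig2 <= 0) { p[k] <- 1; next }
    z <- W - n * m / 2
    cc <- sign(z) * 0.5
    p[k] <- min(1, 2 * stats::pnorm(-abs((z - cc) / sqrt(sig2))))
  }
  p
}
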