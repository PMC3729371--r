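# Two-sample tests and multiple-testing correction.

#' Wilcoxon rank-sum test (normal approximation, tie-corrected)
#'
#' Two-sided rank-sum test on two length samples using the normal
#' approximation with the standard tie correction and no continuity
#' correction.
#'
#' @param a,b numeric samples (non-empty).
#' @return list: \code{statistic} (Mann-Whitney U of \code{a}), \code{z},
#'   \code{p_value}.
#' @export
rankSumTest <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(statistic = U, z = 0, p_value = 1))
  z <- (U - mu) / sqrt(sigma2)
  list(statistic = U, z = z, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Exact two-proportion test (hypergeometric, log-space safe)
#'
#' Conditional exact test of two proportions \code{a/A} vs \code{b/B}
#' (Fisher's construction): one-sided hypergeometric tail probabilities in
#' each direction, computed in log space so that extreme p-values (down to
#' ~1e-300 and below on the log10 scale) are reported without underflow.
#' The two-sided p is the doubled smaller tail, clamped at 1.
#'
#' @param a,A successes and total of the first sample.
#' @param b,B successes and total of the second sample.
#' @return list: \code{p_greater} (first proportion larger), \code{p_less},
#'   \code{p_two_sided}, plus \code{log10_p_greater}, \code{log10_p_less},
#'   \code{log10_p_two_sided}.
#' @export
twoProportionExactTest <- function(a, A, b, B) {
  if (a > A || b > B) stop("successes exceed total")
  if (A <= 0 || B <= 0) stop("empty sample")
  N <- A + B; K <- a + b
  logPG <- stats::phyper(a - 1, K, N - K, A, lower.tail = FALSE, log.p = TRUE)
  logPL <- stats::phyper(a, K, N - K, A, lower.tail = TRUE, log.p = TRUE)
  l10 <- function(lp) lp / log(10)
  logP2 <- min(0, log(2) + min(logPG, logPL))
  list(p_greater = exp(logPG), p_less = exp(logPL), p_two_sided = exp(logP2),
       log10_p_greater = l10(logPG), log10_p_less = l10(logPL),
       log10_p_two_sided = l10(logP2))
}

#' Compare two samples
#'
#' Dispatcher over the package's two-sample tests: \code{"rank_sum"} takes
#' two numeric length samples, \code{"two_proportion_exact"} two
#' (successes, total) pairs.
#'
#' @param sampleA,sampleB numeric vectors (lengths for \code{rank_sum};
#'   \code{c(successes, total)} for \code{two_proportion_exact}).
#' @param test test name.
#' @return the corresponding test result list.
#' @export
compareGroups <- function(sampleA, sampleB,
                          test = c("rank_sum", "two_proportion_exact")) {
  test <- match.arg(test)
  if (test == "rank_sum") rankSumTest(sampleA, sampleB)
  else twoProportionExactTest(sampleA[1L], sampleA[2L], sampleB[1L], sampleB[2L])
}

#' Benjamini-Hochberg adjustment
#' @param p numeric vector of p-values.
#' @return q-values (fdr-adjusted p-values).
#' @export
adjustFdr <- function(p) stats::p.adjust(p, method = "BH")
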