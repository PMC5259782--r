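#' Replicate mean and sample standard deviation
#'
#' The summary used throughout the effector reports ("means ± SD from
#' three independent assays"): arithmetic mean and the n−1 (sample)
#' standard deviation. A single value has no sample SD and is an error.
#'
#' @param values numeric vector, length >= 2.
#' @return tibble with `mean`, `sd`, `n`.
#' @export
mean_sd <- function(values) {
  if (!length(values)) abort("empty input")
  if (length(values) == 1L) {
    abort("sample SD undefined for a single value (need >= 2 replicates)")
  }
  tibble::tibble(mean = mean(values), sd = sd(values), n = length(values))
}

#' Paired two-tailed Student's t-test
#'
#' Wraps [stats::t.test()] with `paired = TRUE`: `t = mean(d) /
#' (sd(d)/sqrt(n))` for differences `d = x − y`, with `n − 1` degrees of
#' freedom and a two-sided p-value. Zero-variance differences (including
#' `x == y`) make the statistic undefined and raise a "degenerate" error
#' rather than returning a spurious p-value.
#'
#' @param x,y numeric vectors of equal length >= 2 (paired replicates).
#' @return tibble with `t_statistic`, `df`, `p_value`.
#' @examples
#' paired_t_test(c(2, 3, 5), c(1, 2, 3))
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2L) abort("need >= 2 pairs")
  d <- x - y
  if (sd(d) == 0) {
    abort("degenerate paired t-test: differences have zero variance")
  }
  res <- t.test(x, y, paired = TRUE, alternative = "two.sided")
  tibble::tibble(t_statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p_value = res$p.value)
}
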