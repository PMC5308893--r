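#' Inferential tests used across the analyses
#'
#' Thin, uniformly-shaped wrappers around the standard tests: paired and
#' two-sample t tests (equal variances), Pearson correlation, two-sample
#' Kolmogorov-Smirnov, and Bonferroni correction. All p-values are
#' two-sided. Each returns a one-row tibble with `statistic`
#' (t, r, or D), `p`, `df`, `n` and `correction`.
#'
#' @param a,b numeric samples (paired inputs must have equal length >= 2).
#' @return one-row tibble (`TestResult`).
#' @export
paired_compare <- function(a, b) {
  if (length(a) != length(b)) abort("paired samples must have equal length")
  d <- a - b
  if (sd(d) < 1e-12 * max(abs(d), 1)) {
    if (max(abs(d)) < 1e-12) return(test_result(0, 1, length(a) - 1, length(a)))
    abort("zero variance of paired differences: statistic undefined")
  }
  ht <- t.test(a, b, paired = TRUE)
  test_result(unname(ht$statistic), ht$p.value, unname(ht$parameter), length(a))
}

#' @rdname paired_compare
#' @export
two_sample_compare <- function(a, b) {
  if (sd(a) == 0 && sd(b) == 0) abort("zero variance in both samples: statistic undefined")
  ht <- t.test(a, b, var.equal = TRUE)
  test_result(unname(ht$statistic), ht$p.value, unname(ht$parameter),
              length(a) + length(b))
}

#' @rdname paired_compare
#' @param x,y numeric vectors for correlation.
#' @export
pearson <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance: correlation undefined")
  ht <- cor.test(x, y, method = "pearson")
  test_result(unname(ht$estimate), ht$p.value, unname(ht$parameter), length(x))
}

#' @rdname paired_compare
#' @export
ks_compare <- function(a, b) {
  ht <- suppressWarnings(ks.test(a, b))
  test_result(unname(ht$statistic), ht$p.value, NA_real_, length(a) + length(b))
}

#' @rdname paired_compare
#' @param p_list vector of p-values.
#' @param m number of comparisons (>= `length(p_list)`).
#' @export
bonferroni <- function(p_list, m = length(p_list)) {
  if (m < length(p_list)) abort("m must be >= length(p_list)")
  pmin(p_list * m, 1)
}

test_result <- function(statistic, p, df, n, correction = "none") {
  tibble(statistic = statistic, p = p, df = df, n = n, correction = correction)
}
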