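# Descriptive hypothesis tests used alongside the mixture analysis:
# Mann-Whitney U, Kruskal-Wallis, Welch t, and Shapiro-Wilk normality.
# All are two-sided and delegate to the standard R implementations behind
# a uniform result record; the U statistic is reported in the
# "number of pairs (a_i > b_j), counting ties as 1/2" convention, which is
# the W statistic of wilcox.test(a, b).

test_result <- function(statistic, p_value, method, exact_p,
                        df = NA_real_, n = NULL) {
  structure(list(statistic = unname(statistic),
                 p_value = unname(p_value), method = method,
                 exact_p = exact_p, df = unname(df), n = n),
            class = "cocco_test")
}

#' @export
print.cocco_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic),
      if (!is.na(x$df)) paste0(", df = ", format(x$df)),
      ", p = ", format.pval(x$p_value),
      if (!x$exact_p) " (normal approximation)", "\n", sep = "")
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. For small tie-free samples the p-value is
#' exact; otherwise the normal approximation with tie correction (and
#' continuity correction, switchable) is used and `exact_p` is `FALSE`.
#'
#' @param a,b numeric samples.
#' @param correct apply the continuity correction in the approximate path
#'   (default `TRUE`).
#' @return a `cocco_test` with the U statistic, p-value, and `exact_p`
#'   flag.
#' @export
mann_whitney_u <- function(a, b, correct = TRUE) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  has_ties <- anyDuplicated(c(a, b)) > 0
  small <- length(a) < 50 && length(b) < 50
  use_exact <- small && !has_ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = correct))
  test_result(res$statistic, res$p.value,
              "Mann-Whitney U test (two-sided)", exact_p = use_exact,
              n = c(n1 = length(a), n2 = length(b)))
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with a chi-square p-value on
#' `length(groups) - 1` degrees of freedom.
#'
#' @param groups a list of numeric vectors.
#' @return a `cocco_test` with the H statistic, df, and p-value.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  res <- stats::kruskal.test(groups)
  test_result(res$statistic, res$p.value,
              "Kruskal-Wallis rank-sum test", exact_p = FALSE,
              df = res$parameter, n = lengths(groups))
}

#' Welch two-sample t-test
#'
#' Two-sided t-test without the equal-variance assumption
#' (Welch-Satterthwaite degrees of freedom).
#'
#' @param a,b numeric samples.
#' @return a `cocco_test` with t, df, and p-value.
#' @export
two_sample_t <- function(a, b) {
  res <- stats::t.test(a, b, var.equal = FALSE)
  test_result(res$statistic, res$p.value,
              "Welch two-sample t-test (two-sided)", exact_p = TRUE,
              df = res$parameter, n = c(n1 = length(a), n2 = length(b)))
}

#' Shapiro-Wilk normality test
#'
#' @param values numeric sample with 3 <= n <= 5000.
#' @return a `cocco_test` with W and p-value.
#' @export
shapiro_wilk <- function(values) {
  res <- stats::shapiro.test(values)
  test_result(res$statistic, res$p.value, "Shapiro-Wilk normality test",
              exact_p = FALSE, n = length(values))
}
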