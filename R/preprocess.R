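# Filtering and descriptive statistics applied before mixture modelling.

#' Single-pass interquartile-range outlier removal
#'
#' Partitions `values` into those inside the two-sided Tukey fences
#' `[Q1 - m * IQR, Q3 + m * IQR]` and those outside. Quartiles use linear
#' interpolation between order statistics (quantile type 7). The rule is
#' applied once: re-running it on the kept values may remove further points,
#' and the pipeline deliberately does not iterate.
#'
#' @param values numeric vector of at least 4 finite values (quartiles of
#'   fewer points are not meaningful for the rule).
#' @param multiplier fence multiplier `m` (default 1.5).
#' @return `list(kept = , removed = )`, both preserving input order;
#'   together they are the input multiset.
#' @export
remove_outliers <- function(values, multiplier = 1.5) {
  if (length(values) < 4) {
    stop("remove_outliers needs at least 4 values (got ", length(values), ")")
  }
  if (any(!is.finite(values))) stop("values must be finite")
  if (!(multiplier > 0)) stop("multiplier must be > 0")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - multiplier * iqr
  hi <- q[2] + multiplier * iqr
  inside <- values >= lo & values <= hi
  list(kept = values[inside], removed = values[!inside],
       fences = c(lower = lo, upper = hi))
}

#' Relative abundance of morphotypes with count margins of error
#'
#' Converts morphotype counts into relative abundances with a
#' normal-approximation (Wald) binomial margin of error,
#' `z * sqrt(p (1 - p) / n)`, at the given confidence level.
#'
#' @param counts named integer vector of morphotype counts; total must be
#'   positive.
#' @param confidence confidence level for the margins (default 0.95).
#' @return a data frame with columns `morphotype`, `count`,
#'   `relative_abundance` (proportion) and `margin_of_error` (proportion).
#'   Proportions sum to 1.
#' @export
relative_abundance <- function(counts, confidence = 0.95) {
  counts <- check_counts(counts)
  total <- sum(counts)
  p <- counts / total
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  data.frame(morphotype = names(counts), count = as.integer(counts),
             relative_abundance = as.numeric(p),
             margin_of_error = as.numeric(z * sqrt(p * (1 - p) / total)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exclude rare morphotypes
#'
#' Returns the morphotypes whose relative abundance in the sample is at
#' least `threshold`; morphotypes strictly below it (default: below 1%) are
#' excluded from the mixture model.
#'
#' @param counts named integer vector of morphotype counts.
#' @param threshold minimum relative abundance (default 0.01).
#' @return character vector of retained morphotype names, in input order.
#' @export
filter_rare <- function(counts, threshold = 0.01) {
  counts <- check_counts(counts)
  names(counts)[counts / sum(counts) >= threshold]
}

check_counts <- function(counts) {
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stop("counts must be a named vector (names = morphotypes)")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (sum(counts) <= 0) stop("total count must be > 0")
  counts
}

#' Mean with a t-based confidence half-width
#'
#' @param values numeric vector, n >= 2.
#' @param confidence confidence level (default 0.95).
#' @return a data frame row with `n`, `mean` and `ci_half_width` (same
#'   units as the input; 0 for a constant sequence).
#' @export
summarize_values <- function(values, confidence = 0.95) {
  n <- length(values)
  if (n < 2) stop("summarize_values needs n >= 2")
  if (any(!is.finite(values))) stop("values must be finite")
  half <- stats::qt(1 - (1 - confidence) / 2, df = n - 1) *
    stats::sd(values) / sqrt(n)
  data.frame(n = n, mean = mean(values), ci_half_width = half)
}
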