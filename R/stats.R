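# Group-comparison statistics: the classical tests plus a from-scratch
# all-pairs Steel-Dwass nonparametric multiple comparison.

#' Significance label for a p-value
#'
#' Convention: P > 0.05 is "n.s.", P < 0.05 "*", P < 0.01 "**",
#' P < 0.001 "***".
#'
#' @param p P-value in [0, 1].
#' @return Character label.
#' @export
significance_label <- function(p) {
  vapply(p, function(pp) {
    if (!is.finite(pp) || pp < 0 || pp > 1) stop("p-value must lie in [0, 1]")
    if (pp < 0.001) "***" else if (pp < 0.01) "**" else if (pp < 0.05) "*" else "n.s."
  }, character(1L))
}

.test_result <- function(test_name, statistic, p_value, tails, groups) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), tails = tails, groups = groups,
                 significance_label = significance_label(p_value)),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s (%s-tailed): statistic = %.4g, P = %.4g %s\n",
              x$test_name, x$tails, x$statistic, x$p_value,
              x$significance_label))
  invisible(x)
}

#' Classical one- and two-sample tests with significance labels
#'
#' Thin, validated wrappers around the standard implementations:
#' two-sample t (pooled variance by default, Welch optional), the variance
#' F-test, the asymptotic two-sample Kolmogorov-Smirnov test, and the
#' Shapiro-Wilk normality test. One-tailed t-tests take the direction from
#' \code{tail}.
#'
#' @param x Numeric sample.
#' @param y Second sample (not used by \code{shapiro}).
#' @param kind One of \code{"t_two"}, \code{"t_one"}, \code{"f_var"},
#'   \code{"ks_two"}, \code{"shapiro"}.
#' @param tail For \code{t_one}: \code{"less"} or \code{"greater"} (mean of
#'   \code{x} relative to \code{y}).
#' @param welch Use the Welch t-test instead of pooled variance.
#' @return A \code{"test_result"}: test name, statistic, p-value, tails,
#'   groups, significance label.
#' @export
classic_test <- function(x, y = NULL, kind = c("t_two", "t_one", "f_var",
                                               "ks_two", "shapiro"),
                         tail = c("less", "greater"), welch = FALSE) {
  kind <- match.arg(kind)
  x <- as.numeric(x)
  two_sample <- kind != "shapiro"
  if (two_sample) {
    if (is.null(y)) stop(kind, " needs two samples")
    y <- as.numeric(y)
    if (length(x) < 2L || length(y) < 2L) stop(kind, " needs n >= 2 per sample")
  }
  switch(kind,
    t_two = , t_one = {
      if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
        # degenerate but well-defined: identical constant samples
        return(.test_result("t-test", 0, 1, "two", c("x", "y")))
      }
      alt <- if (kind == "t_two") "two.sided" else match.arg(tail)
      ht <- stats::t.test(x, y, alternative = alt, var.equal = !welch)
      .test_result(if (welch) "Welch t-test" else "t-test",
                   ht$statistic, ht$p.value,
                   if (kind == "t_two") "two" else "one", c("x", "y"))
    },
    f_var = {
      if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("F-test undefined for a constant sample")
      ht <- stats::var.test(x, y)
      .test_result("F-test", ht$statistic, ht$p.value, "two", c("x", "y"))
    },
    ks_two = {
      ht <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
      .test_result("Kolmogorov-Smirnov test", ht$statistic, ht$p.value,
                   "two", c("x", "y"))
    },
    shapiro = {
      if (length(x) < 3L || length(x) > 5000L)
        stop("Shapiro-Wilk needs 3 <= n <= 5000")
      if (stats::sd(x) == 0) stop("Shapiro-Wilk undefined for a constant sample")
      ht <- stats::shapiro.test(x)
      .test_result("Shapiro-Wilk test", ht$statistic, ht$p.value, "two", "x")
    })
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every pair of groups, the joint mid-ranks (tie-corrected) of the two
#' samples give a standardized Wilcoxon rank-sum statistic \eqn{z}; the
#' familywise p-value refers \eqn{\sqrt{2}|z|} to the studentized-range
#' distribution with \eqn{k} groups and infinite degrees of freedom,
#' \eqn{p = P(Q_{k,\infty} \ge \sqrt{2}|z|)}.
#'
#' @param groups Named list of k >= 3 numeric samples (each n >= 2).
#' @return Data frame with one row per pair: \code{group1}, \code{group2},
#'   \code{statistic} (z), \code{p_value}, \code{significance_label}.
#' @export
steel_dwass <- function(groups) {
  if (is.data.frame(groups)) stop("pass a named list of numeric vectors")
  k <- length(groups)
  if (k < 3L)
    stop("Steel-Dwass needs k >= 3 groups; use a rank-sum test for two groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("group", seq_len(k))
  if (any(vapply(groups, length, 1L) < 2L)) stop("every group needs n >= 2")
  pairs <- utils::combn(k, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    x <- groups[[i1]]; y <- groups[[i2]]
    n1 <- length(x); n2 <- length(y); N <- n1 + n2
    r <- rank(c(x, y))                          # mid-ranks under ties
    R1 <- sum(r[seq_len(n1)])
    E <- n1 * (N + 1) / 2
    V <- n1 * n2 / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
    z <- if (V > 0) (R1 - E) / sqrt(V) else 0
    p <- stats::ptukey(sqrt(2) * abs(z), nmeans = k, df = Inf,
                       lower.tail = FALSE)
    data.frame(group1 = names(groups)[i1], group2 = names(groups)[i2],
               statistic = z, p_value = p,
               significance_label = significance_label(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Percent difference of a test mean relative to a reference mean
#'
#' \eqn{100 (\bar{x}_{ref} - \bar{x}_{test}) / \bar{x}_{ref}}; positive
#' values mean the test group is smaller (thinner) than the reference.
#'
#' @param reference_mean Positive reference group mean.
#' @param test_mean Test group mean.
#' @return Percent difference.
#' @export
percent_difference <- function(reference_mean, test_mean) {
  if (!is.finite(reference_mean) || reference_mean <= 0)
    stop("reference mean must be positive")
  100 * (reference_mean - test_mean) / reference_mean
}
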