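#' Pearson chi-squared test on a 2x2 responder table
#'
#' Compares responder frequencies between two conditions (rows) with the
#' Pearson chi-squared test on the 2x2 table of responsive / non-responsive
#' counts, df = 1, without Yates continuity correction — the variant whose
#' statistic equals the classic `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`.
#'
#' @param a,b First row: responsive / non-responsive counts.
#' @param c,d Second row.
#' @return A `ca_test` list: `statistic`, `p_value`, `method`, `df`, `n`,
#'   `exact = FALSE`.
#' @examples
#' chisq_2x2(44, 5, 40, 7)   # retention with vs without blocker
#' @export
chisq_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("chisq_2x2 requires non-negative integer counts")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected == 0))
    stop("degenerate table: an expected cell count is 0")
  ht <- stats::chisq.test(tab, correct = FALSE)
  ca_test(statistic = unname(ht$statistic), p_value = ht$p.value,
          method = "Pearson chi-squared (no continuity correction)",
          n = n, exact = FALSE, df = 1L)
}

#' Wilcoxon-Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. The p-value is
#' exact (full permutation distribution of the rank sum) when the smaller
#' sample has at most `exact_max` observations and there are no ties;
#' otherwise the normal approximation with the tie correction is used.
#'
#' @param x,y Numeric samples.
#' @param exact_max Largest `min(n1, n2)` for which the exact distribution
#'   is used (default 8).
#' @return A `ca_test` list with the U statistic (`statistic`), `p_value`,
#'   `n1`, `n2`, and `exact`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  if (!length(x) || !length(y)) stop("mann_whitney_u: empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && min(length(x), length(y)) <= exact_max
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = !use_exact))
  ca_test(statistic = unname(ht$statistic), p_value = min(1, ht$p.value),
          method = if (use_exact) "Mann-Whitney U (exact)" else
            "Mann-Whitney U (normal approximation, tie-corrected)",
          n = c(n1 = length(x), n2 = length(y)), exact = use_exact)
}

#' One-sample sign test
#'
#' Exact binomial test on the number of observations above `null_median`
#' after dropping exact ties; two-sided p-value is twice the smaller
#' binomial tail, capped at 1. Used e.g. to test whether normalized
#' dose-response peaks differ from the reference value 1.
#'
#' @param x Numeric sample.
#' @param null_median Hypothesized median (default 1).
#' @return A `ca_test` list: `statistic` is the count above the null
#'   median, `n` the tie-free sample size, `exact = TRUE`.
#' @export
sign_test <- function(x, null_median = 1) {
  x <- x[!is.na(x)]
  above <- sum(x > null_median)
  below <- sum(x < null_median)
  n <- above + below
  if (n == 0)
    stop("undefined test: all observations tie the null median")
  p <- min(1, 2 * min(stats::pbinom(above, n, 0.5),
                      1 - stats::pbinom(above - 1, n, 0.5)))
  ca_test(statistic = above, p_value = p,
          method = "one-sample sign test (exact binomial)",
          n = n, exact = TRUE)
}

#' Normality gate for test routing
#'
#' Flags a sample as non-normal when either the Shapiro-Wilk or the
#' Jarque-Bera test rejects at `alpha`; non-normal samples are routed to
#' the nonparametric tests ([mann_whitney_u()], [sign_test()]).
#'
#' @param x Numeric sample (n >= 3, non-degenerate).
#' @param alpha Significance level of the gate (default 0.05).
#' @return List `non_normal` (logical), `shapiro_p`, `jarque_bera_p`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("normality_gate needs n >= 3")
  if (stats::sd(x) == 0) stop("normality_gate: degenerate (constant) sample")
  sw <- stats::shapiro.test(x)$p.value
  jb <- jarque_bera(x)$p_value
  list(non_normal = sw < alpha || jb < alpha,
       shapiro_p = sw, jarque_bera_p = jb)
}

#' Jarque-Bera normality test
#'
#' Moment-based test of normality: `JB = n/6 * (S^2 + (K - 3)^2 / 4)` with
#' sample skewness `S` and kurtosis `K` (biased moment estimators), referred
#' to the chi-squared distribution with 2 degrees of freedom.
#'
#' @param x Numeric sample (n >= 3).
#' @return A `ca_test` list.
#' @export
jarque_bera <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("jarque_bera needs n >= 3")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("jarque_bera: degenerate (constant) sample")
  s <- mean((x - m)^3) / m2^1.5
  k <- mean((x - m)^4) / m2^2
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  ca_test(statistic = jb, p_value = stats::pchisq(jb, df = 2,
                                                  lower.tail = FALSE),
          method = "Jarque-Bera", n = n, exact = FALSE)
}

ca_test <- function(statistic, p_value, method, n, exact, df = NULL) {
  stopifnot(is.finite(statistic), p_value >= 0, p_value <= 1)
  structure(list(statistic = statistic, p_value = p_value, method = method,
                 n = n, exact = exact, df = df), class = "ca_test")
}

#' @export
print.ca_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %s%s)\n", x$method,
              x$statistic, x$p_value, paste(x$n, collapse = ", "),
              if (x$exact) ", exact" else ""))
  invisible(x)
}
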