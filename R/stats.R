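# Summary statistics used by the feasibility analyses, implemented from
# their defining formulas: Pearson chi-square on r x c contingency tables
# (no continuity correction -- the dialect that reproduces the published
# 2x2 statistics), pooled two-sample t from group summaries, paired t on
# difference scores, Pearson correlation, and adherence-funnel percentages.

new_test_result <- function(statistic, df, p, method, extra = list()) {
  structure(
    c(list(statistic = statistic, parameter = c(df = df), p.value = p,
           method = method, data.name = ""), extra),
    class = "htest"
  )
}

#' Pearson chi-square test on a contingency table
#'
#' Computes the uncorrected Pearson statistic
#' \eqn{\sum (O - E)^2 / E} with expected counts from the row/column
#' margins, df = (r-1)(c-1), and the upper-tail chi-square p-value. No
#' Yates continuity correction is applied.
#'
#' @param counts matrix (or table / data.frame of counts) of non-negative
#'   integers, at least 2x2.
#' @return an object of class \code{htest} with fields \code{statistic},
#'   \code{parameter} (df), \code{p.value}, \code{observed},
#'   \code{expected}.
#' @examples
#' chi_square(matrix(c(1055, 292, 519, 203), nrow = 2))
#' @export
chi_square <- function(counts) {
  x <- as.matrix(counts)
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop("contingency table must hold non-negative counts", call. = FALSE)
  }
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  n <- sum(x)
  if (n <= 0) stop("contingency table has zero grand total", call. = FALSE)
  expected <- outer(rowSums(x), colSums(x)) / n
  if (any(expected == 0)) {
    stop("degenerate margins: zero expected cell", call. = FALSE)
  }
  stat <- sum((x - expected)^2 / expected)
  df <- (nrow(x) - 1) * (ncol(x) - 1)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  new_test_result(c(`X-squared` = stat), df, p,
                  "Pearson chi-square (no continuity correction)",
                  list(observed = x, expected = expected))
}

#' Pooled two-sample Student t test from group summaries
#'
#' Student's t with the pooled variance estimate and df = n1 + n2 - 2
#' (matching the published df pattern), two-tailed p. Works from the group
#' means, SDs and sizes, so published summary rows can be re-tested.
#'
#' @param m1,s1,n1 mean, SD and size of group 1.
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return an \code{htest} with the t statistic, df and two-tailed p.
#' @export
two_sample_t_pooled <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (s1 < 0 || s2 < 0) stop("SDs must be non-negative", call. = FALSE)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 == 0) {
    if (m1 != m2) {
      stop("zero pooled variance with unequal means", call. = FALSE)
    }
    t_stat <- 0
  } else {
    t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- 2 * stats::pt(-abs(t_stat), df)
  new_test_result(c(t = t_stat), df, p,
                  "Two-sample Student t (pooled variance)")
}

#' Paired t test on difference scores
#'
#' \eqn{t = \bar d \sqrt{n} / s_d}, df = n - 1, two-tailed p; used for the
#' pre/post outcome comparisons.
#'
#' @param differences numeric vector of within-user differences
#'   (post - pre), length >= 2 with non-zero SD.
#' @return an \code{htest} with the t statistic, df and two-tailed p.
#' @export
paired_t <- function(differences) {
  n <- length(differences)
  if (n < 2) stop("paired t needs at least 2 differences", call. = FALSE)
  s <- stats::sd(differences)
  if (s == 0) {
    stop("constant differences: paired t is undefined", call. = FALSE)
  }
  t_stat <- mean(differences) * sqrt(n) / s
  p <- 2 * stats::pt(-abs(t_stat), n - 1)
  new_test_result(c(t = t_stat), n - 1, p,
                  "Paired t on difference scores",
                  list(estimate = c(`mean difference` = mean(differences))))
}

#' Pearson product-moment correlation with t-based test
#'
#' r from the sample covariance and variances; the test uses
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on n - 2 df, two-tailed.
#'
#' @param x,y numeric vectors of equal length >= 3, each with non-zero
#'   variance.
#' @return an \code{htest} with \code{estimate} r, the t statistic, df and
#'   two-tailed p (0 when |r| = 1).
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  dx <- x - mean(x)
  dy <- y - mean(y)
  vx <- sum(dx^2)
  vy <- sum(dy^2)
  if (vx == 0 || vy == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- sum(dx * dy) / sqrt(vx * vy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    t_stat <- sign(r) * Inf
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), n - 2)
  }
  new_test_result(c(t = t_stat), n - 2, p, "Pearson correlation",
                  list(estimate = c(r = r)))
}

#' Adherence-funnel percentages
#'
#' For monotone non-increasing stage counts, reports each stage's
#' percentage of the previous stage (conditional completion rate) and of
#' the first stage (overall fraction), rounded to one decimal.
#'
#' @param counts named numeric vector of stage counts, first stage first.
#' @return data.frame with columns stage, count, pct_of_previous,
#'   pct_of_first.
#' @examples
#' funnel_percentages(c(downloaded = 2069, screened = 1574))
#' @export
funnel_percentages <- function(counts) {
  if (length(counts) < 1 || anyNA(counts) || any(counts < 0)) {
    stop("funnel counts must be non-negative", call. = FALSE)
  }
  if (any(diff(counts) > 0)) {
    stop("funnel counts must be monotone non-increasing", call. = FALSE)
  }
  if (counts[1] == 0) {
    stop("empty first stage: percentages undefined", call. = FALSE)
  }
  prev <- c(NA, counts[-length(counts)])
  if (any(prev == 0 & counts > 0, na.rm = TRUE)) {
    stop("division by zero: empty upstream stage", call. = FALSE)
  }
  pct_prev <- ifelse(is.na(prev), NA,
                     ifelse(prev == 0, 0, 100 * counts / prev))
  data.frame(
    stage = if (is.null(names(counts))) {
      paste0("stage", seq_along(counts))
    } else names(counts),
    count = as.numeric(counts),
    pct_of_previous = round(pct_prev, 1),
    pct_of_first = round(100 * counts / counts[1], 1),
    row.names = NULL
  )
}
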