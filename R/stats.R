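# Rank and association statistics used across the atlas and peptide modules.

#' Mann-Whitney (Wilcoxon rank-sum) test with exact small-sample p
#'
#' Computes the rank-sum statistic U for group `a` versus group `b`. When
#' `length(a) + length(b) <= exact_limit` the p-value is exact, obtained by
#' full enumeration of all `choose(m + n, m)` group labelings of the pooled
#' values (valid under ties); otherwise a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param two_sided Two-sided p (default) or one-sided (`a` tends larger).
#' @param exact_limit Maximum pooled size for enumeration (default 12).
#' @return List with `U` (for group `a`), `p`, and `method`.
#' @export
mann_whitney_exact <- function(a, b, two_sided = TRUE, exact_limit = 12) {
  if (!length(a) || !length(b)) abort("mann_whitney_exact: empty group")
  m <- length(a); n <- length(b)
  u_stat <- function(ga, gb) {
    r <- rank(c(ga, gb))
    sum(r[seq_along(ga)]) - length(ga) * (length(ga) + 1) / 2
  }
  U <- u_stat(a, b)
  mu <- m * n / 2
  if (m + n <= exact_limit) {
    pool <- c(a, b)
    idx <- utils::combn(m + n, m)
    us <- apply(idx, 2, function(i) u_stat(pool[i], pool[-i]))
    if (two_sided) {
      p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    } else {
      p <- mean(us >= U - 1e-12)
    }
    return(list(U = U, p = p, method = "exact enumeration"))
  }
  # normal approximation with tie correction
  r <- rank(c(a, b))
  N <- m + n
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- m * n / 12 * (N + 1 - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal approximation"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- if (two_sided) 2 * pnorm(-abs(z)) else pnorm(-z, lower.tail = FALSE)
  list(U = U, p = min(1, p), method = "normal approximation")
}

#' Chi-squared test (goodness of fit or contingency)
#'
#' With a vector `observed` and `expected_prop`, performs a goodness-of-fit
#' test of the observed counts against expected proportions (df = k - 1).
#' With a matrix `observed` (and `expected_prop = NULL`), performs the usual
#' contingency test with expected counts from the margins
#' (df = (r - 1)(c - 1)).
#'
#' @param observed Non-negative counts, vector or matrix.
#' @param expected_prop Expected proportions (vector case); normalised to 1.
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chi_squared <- function(observed, expected_prop = NULL) {
  if (is.matrix(observed)) {
    expected <- outer(rowSums(observed), colSums(observed)) / sum(observed)
    df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  } else {
    if (is.null(expected_prop)) abort("expected proportions required for goodness-of-fit")
    expected_prop <- expected_prop / sum(expected_prop)
    expected <- expected_prop * sum(observed)
    df <- length(observed) - 1
  }
  if (any(expected <= 0)) abort("chi_squared: zero expected cell")
  statistic <- sum((observed - expected)^2 / expected)
  list(statistic = statistic, df = df,
       p = pchisq(statistic, df, lower.tail = FALSE), expected = expected)
}

#' Kendall tau-b correlation with normal-approximation p
#'
#' Tie-corrected tau-b via [stats::cor.test()]. Constant input is signalled
#' as an error rather than returning `NA`.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @param conf_level Confidence level retained for reporting (default 0.95).
#' @return List with `tau`, `p`, `conf_level`.
#' @export
kendall_tau <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y) || length(x) < 2) abort("kendall_tau: need equal lengths >= 2")
  if (sd(x) == 0 || sd(y) == 0) abort("kendall_tau: undefined for constant input")
  ct <- suppressWarnings(cor.test(x, y, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p = ct$p.value, conf_level = conf_level)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3, non-constant.
#' @return The correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) abort("pearson: need equal lengths >= 3")
  if (sd(x) == 0 || sd(y) == 0) abort("pearson: undefined for constant input")
  unname(cor(x, y))
}
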