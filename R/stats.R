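#' Friedman repeated-measures test
#'
#' Nonparametric test for differences between k repeated conditions
#' measured on N subjects. Values are ranked within subject (mid-ranks for
#' ties) and the statistic is
#' `chi2 = 12/(N k (k+1)) * sum(Rj^2) - 3 N (k+1)` with `Rj` the column
#' rank sums. The tie-corrected statistic (chi2 divided by
#' `1 - sum(t^3 - t) / (N k (k^2 - 1))`) drives the p value against the
#' chi-square distribution with k-1 degrees of freedom; the uncorrected
#' statistic is retained because Kendall's w is defined from it.
#'
#' @param values N x k numeric matrix (subjects x conditions), no missing
#'   cells.
#' @return An object of class `friedman_result`: `chi2` (tie-corrected),
#'   `chi2_uncorrected`, `df`, `p`, `n`, `k`, `w` (Kendall's concordance
#'   from the uncorrected statistic) and `w_label`.
#' @export
friedman_rm <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("missing cells are not allowed")
  n <- nrow(values); k <- ncol(values)
  if (k < 2) stop("at least 2 conditions are required")
  if (n < 2) stop("at least 2 subjects are required")
  ranks <- t(apply(values, 1, rank))
  rj <- colSums(ranks)
  chi2_unc <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  ties <- sum(apply(values, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  corr <- 1 - ties / (n * k * (k^2 - 1))
  chi2 <- if (corr > 0) chi2_unc / corr else NA_real_
  p <- if (is.na(chi2)) 1 else stats::pchisq(chi2, k - 1, lower.tail = FALSE)
  w <- kendalls_w(chi2_unc, n, k)
  structure(list(chi2 = chi2, chi2_uncorrected = chi2_unc, df = k - 1,
                 p = p, n = n, k = k, w = as.numeric(w),
                 w_label = attr(w, "label")),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman test: chi2(%d) = %.3f, p = %.4g, Kendall's w = %.3f (%s)\n",
              x$df, x$chi2, x$p, x$w, x$w_label))
  invisible(x)
}

#' Kendall's coefficient of concordance
#'
#' Effect size for the Friedman test: `w = chi2 / (N (k - 1))`, where
#' `chi2` is the (tie-uncorrected) Friedman statistic, `N` the sample size
#' and `k` the number of repeated measurements. Interpretation bands:
#' 0.1 to <0.3 small, 0.3 to <0.5 moderate, >=0.5 large effect.
#'
#' @param chi2 Friedman chi-square statistic (>= 0).
#' @param n Sample size.
#' @param k Number of repeated measurements (>= 2).
#' @return w, with the interpretation attached as attribute `"label"`.
#' @export
#' @examples
#' round(kendalls_w(20.67, 21, 3), 2)  # 0.49
kendalls_w <- function(chi2, n, k) {
  if (k < 2) stop("k must be at least 2")
  if (n < 1 || chi2 < 0) stop("invalid inputs")
  w <- chi2 / (n * (k - 1))
  label <- if (w < 0.1) "negligible" else if (w < 0.3) "small" else
    if (w < 0.5) "moderate" else "large"
  structure(w, label = label)
}

#' Tukey post-hoc comparisons on Friedman ranks
#'
#' All-pairs comparison of mean within-subject ranks using the studentized
#' range distribution: for conditions i, j the statistic is
#' `q = |Rbar_i - Rbar_j| / sqrt(k (k+1) / (12 N))` referred to the
#' studentized range with k groups and infinite error degrees of freedom.
#'
#' @param values N x k matrix (subjects x conditions).
#' @return Data frame with columns `i`, `j`, `mean_rank_diff`, `p`.
#' @export
tukey_posthoc <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (k < 2) stop("at least 2 conditions are required")
  rbar <- colMeans(t(apply(values, 1, rank)))
  se <- sqrt(k * (k + 1) / (12 * n))
  pairs <- utils::combn(k, 2)
  labs <- colnames(values)
  if (is.null(labs)) labs <- paste0("cond", seq_len(k))
  data.frame(
    i = labs[pairs[1, ]], j = labs[pairs[2, ]],
    mean_rank_diff = rbar[pairs[1, ]] - rbar[pairs[2, ]],
    p = stats::ptukey(abs(rbar[pairs[1, ]] - rbar[pairs[2, ]]) / se,
                      nmeans = k, df = Inf, lower.tail = FALSE),
    row.names = NULL)
}

#' Intraclass correlation, absolute agreement, single measurement
#'
#' Two-way model ICC for agreement between two (or more) measurement
#' methods across subjects, in the absolute-agreement, single-measurement
#' form: `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, where MSR,
#' MSC and MSE are the rows (subjects), columns (methods) and error mean
#' squares of the two-way ANOVA. Absolute agreement penalises systematic
#' offsets between methods, unlike the consistency form. Guideline bands:
#' <0.5 poor, 0.5-0.75 moderate, 0.75-0.9 good, >0.9 excellent.
#'
#' @param pairs N x k matrix (subjects x methods), k >= 2, N >= 3.
#' @return List with `icc`, `icc_label`, the ANOVA mean squares, and a
#'   `flags` field (zero total variance makes the ICC undefined).
#' @export
icc_absolute_single <- function(pairs) {
  m <- as.matrix(pairs)
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("at least 3 subjects are required")
  mu <- mean(m)
  msr <- k * sum((rowMeans(m) - mu)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - mu)^2) / (k - 1)
  sse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + mu)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom <= 0 || (msr == 0 && msc == 0 && mse == 0))
    return(list(icc = NA_real_, icc_label = NA_character_, msr = msr,
                msc = msc, mse = mse, flags = "zero total variance"))
  icc <- (msr - mse) / denom
  label <- if (icc < 0.5) "poor" else if (icc < 0.75) "moderate" else
    if (icc <= 0.9) "good" else "excellent"
  list(icc = icc, icc_label = label, msr = msr, msc = msc, mse = mse,
       flags = character(0))
}

#' TOST equivalence by the 90% confidence-interval inclusion rule
#'
#' Two one-sided tests at alpha = 0.05, presented as the 90% two-sided t
#' confidence interval for the paired mean difference: equivalence is
#' declared when the interval lies entirely within `(-bounds, +bounds)`
#' (prespecified equivalence bounds, default +/- 1 mA).
#'
#' @param diffs Paired differences (mA).
#' @param bounds Equivalence half-width (mA).
#' @return List with `mean_diff`, `ci90` (`c(low, high)`), `bounds` and
#'   `equivalent`.
#' @export
tost_equivalence <- function(diffs, bounds = 1.0) {
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 3) stop("at least 3 paired differences are required")
  m <- mean(diffs); s <- stats::sd(diffs)
  half <- if (s == 0) 0 else stats::qt(0.95, n - 1) * s / sqrt(n)
  ci <- c(m - half, m + half)
  list(mean_diff = m, ci90 = ci, bounds = bounds,
       equivalent = ci[1] > -bounds && ci[2] < bounds)
}

#' Bland-Altman limits of agreement
#'
#' @param a,b Paired measurements (same length), or `b` missing and `a` a
#'   two-column matrix.
#' @return List with `bias` (mean difference) and `loa` (bias +/- 1.96 sd
#'   of the differences).
#' @export
bland_altman <- function(a, b = NULL) {
  if (is.null(b)) { b <- a[, 2]; a <- a[, 1] }
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  if (length(d) < 2 || is.na(s)) s <- 0
  list(bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s))
}
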