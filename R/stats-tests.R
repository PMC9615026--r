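# Two-sample tests applied to per-cell metrics.

#' Welch's two-sample t test (two-tailed, unpaired)
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom.
#' Degenerate inputs are handled explicitly: two zero-variance groups with
#' equal means give t = 0, p = 1; with unequal means, p = 0 with a warning.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @return An \code{htest}-style list with \code{statistic} (t),
#'   \code{parameter} (df), \code{p.value}, \code{estimate} (group means) and
#'   \code{nPerGroup}.
#' @examples
#' welchTTest(c(1, 2, 3), c(2, 3, 4))
#' @export
welchTTest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  va <- stats::var(a); vb <- stats::var(b)
  ma <- mean(a); mb <- mean(b)
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      t <- 0; df <- NA_real_; p <- 1
    } else {
      warning("both groups have zero variance with unequal means")
      t <- sign(ma - mb) * Inf; df <- NA_real_; p <- 0
    }
  } else {
    se2 <- va / length(a) + vb / length(b)
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(statistic = c(t = t), parameter = c(df = df),
                 p.value = p, estimate = c(meanA = ma, meanB = mb),
                 nPerGroup = c(length(a), length(b)),
                 method = "Welch two-sample t test (two-tailed)",
                 data.name = "a vs b"),
            class = "htest")
}

#' Mann-Whitney U test (two-tailed)
#'
#' Exact two-tailed p-value for small tie-free samples
#' (\code{n_a + n_b <= 12}); otherwise the normal approximation with tie
#' correction. Which path was used is recorded in \code{method}.
#'
#' @param a,b Numeric vectors (each n >= 1).
#' @return An \code{htest}-style list; \code{statistic} is the U statistic
#'   for the first group.
#' @examples
#' mannWhitneyTest(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyTest <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("empty group")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact))
  structure(list(statistic = c(U = unname(wt$statistic)),
                 parameter = c(df = NA_real_),
                 p.value = wt$p.value,
                 nPerGroup = c(length(a), length(b)),
                 method = paste0("Mann-Whitney U test (",
                                 if (exact) "exact"
                                 else "normal approximation, tie-corrected",
                                 ")"),
                 data.name = "a vs b"),
            class = "htest")
}

#' Tukey box-and-whisker summary
#'
#' Quartiles use linear interpolation of the empirical CDF (the "type 7"
#' convention, fixed for determinism); whiskers extend to the most extreme
#' points within 1.5 x IQR of the quartiles; points beyond are outliers.
#'
#' @param values Numeric vector (n >= 1).
#' @return List of class \code{"tukeyBoxSummary"}: \code{median}, \code{q1},
#'   \code{q3}, \code{iqr}, \code{whiskerLow}, \code{whiskerHigh},
#'   \code{outliers}.
#' @examples
#' tukeyBoxSummary(c(1, 2, 3, 4, 100))  # Q1 2, Q3 4, outlier 100
#' @export
tukeyBoxSummary <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("n >= 1 required")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7L)
  iqr <- q[3L] - q[1L]
  loFence <- q[1L] - 1.5 * iqr
  hiFence <- q[3L] + 1.5 * iqr
  inFence <- values >= loFence & values <= hiFence
  structure(list(median = q[2L], q1 = q[1L], q3 = q[3L], iqr = iqr,
                 whiskerLow = if (any(inFence)) min(values[inFence]) else NA_real_,
                 whiskerHigh = if (any(inFence)) max(values[inFence]) else NA_real_,
                 outliers = sort(values[!inFence])),
            class = "tukeyBoxSummary")
}

#' @export
print.tukeyBoxSummary <- function(x, ...) {
  cat(sprintf("Tukey box summary: median %.4g [Q1 %.4g, Q3 %.4g]\n",
              x$median, x$q1, x$q3))
  cat(sprintf("  whiskers [%.4g, %.4g]; %d outlier(s)\n",
              x$whiskerLow, x$whiskerHigh, length(x$outliers)))
  invisible(x)
}
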