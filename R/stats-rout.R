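# ROUT outlier detection (Q = false discovery rate in percent) adapted to a
# one-parameter constant model for univariate group data: a robust center is
# fit by iteratively reweighted least squares (bisquare), residual scale is
# the RSDR (68.27th percentile of absolute residuals with a small-sample
# correction), residuals get t-based p-values, and outliers are declared by
# an FDR-controlled step-up rule testing from the most extreme residual
# inward (at most the most extreme 30% of points are eligible).

#' ROUT outlier detection on a data column
#'
#' @param values Numeric vector (n >= 3).
#' @param Q Maximum false discovery rate in percent, in (0, 100); the
#'   conventional setting is 1.
#' @return List of class \code{"routOutliers"}: \code{kept}, \code{flagged},
#'   \code{flaggedIndex}, \code{center} (robust center estimate),
#'   \code{rsdr}, \code{Q}.
#' @examples
#' set.seed(2)
#' routOutliers(c(rnorm(14), 100), Q = 1)
#' @export
routOutliers <- function(values, Q = 1) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L) stop("n >= 3 required")
  if (Q <= 0 || Q >= 100) stop("Q must be in (0, 100)")
  if (stats::mad(values) == 0 && stats::sd(values) == 0) {
    return(structure(list(kept = values, flagged = numeric(0),
                          flaggedIndex = integer(0),
                          center = values[1L], rsdr = 0, Q = Q),
                     class = "routOutliers"))
  }
  center <- tryCatch(
    as.numeric(stats::coef(suppressWarnings(
      MASS::rlm(values ~ 1, psi = MASS::psi.bisquare, maxit = 100L)))),
    error = function(e) stats::median(values))
  res <- values - center
  rsdr <- stats::quantile(abs(res), 0.6827, names = FALSE, type = 7L) *
    n / (n - 1)
  ord <- order(abs(res), decreasing = TRUE)
  nTest <- max(1L, floor(0.3 * n))
  flagged <- integer(0)
  if (rsdr == 0) {
    # degenerate scale: every nonzero residual is infinitely surprising
    flagged <- ord[abs(res[ord]) > 0][seq_len(min(nTest, sum(abs(res) > 0)))]
  } else {
    tScores <- abs(res[ord]) / rsdr
    pvals <- 2 * stats::pt(-tScores, df = n - 1)
    # step-up: find the largest i (within the 30% cap) with
    # p_(i) <= (i / n) * Q / 100, flag residuals 1..i
    iMax <- 0L
    for (i in seq_len(nTest))
      if (pvals[i] <= (i / n) * Q / 100) iMax <- i
    if (iMax > 0L) flagged <- ord[seq_len(iMax)]
  }
  structure(list(kept = values[setdiff(seq_len(n), flagged)],
                 flagged = values[flagged],
                 flaggedIndex = sort(flagged),
                 center = center, rsdr = rsdr, Q = Q),
            class = "routOutliers")
}

#' @export
print.routOutliers <- function(x, ...) {
  cat(sprintf("ROUT (Q = %g%%): %d of %d value(s) flagged\n",
              x$Q, length(x$flagged), length(x$kept) + length(x$flagged)))
  if (length(x$flagged))
    cat("  flagged:", paste(format(x$flagged, digits = 4), collapse = ", "),
        "\n")
  cat(sprintf("  robust center %.4g, RSDR %.4g\n", x$center, x$rsdr))
  invisible(x)
}
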