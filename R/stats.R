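#' Normality check by one-sample Kolmogorov-Smirnov test
#'
#' Standardises the sample by its own mean and standard deviation and tests
#' it against the standard normal. The series is treated as normal when the
#' KS p-value is at least `alpha`. Estimating the reference parameters from
#' the sample makes the test conservative in small samples (p-values are
#' biased high); this matches the conventional usage the pipeline gates its
#' correlation choice on.
#'
#' @param x numeric vector, at least 8 non-missing values.
#' @param alpha significance level (default 0.05).
#' @return logical (`TRUE` = consistent with normality) with attribute
#'   `p_value`.
#' @export
test_normality <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 8L) stop("need at least 8 observations for the normality test")
  s <- stats::sd(x)
  if (s == 0) stop("zero-variance sample")
  z <- (x - mean(x)) / s
  p <- suppressWarnings(stats::ks.test(z, "pnorm")$p.value)
  structure(p >= alpha, p_value = p)
}

#' Normality-gated correlation between two series
#'
#' Pairwise-deletes missing values, then correlates with Pearson's product
#' moment when both series pass the KS normality check and with Spearman's
#' rank correlation otherwise (two-sided p-values in both cases). The
#' least-squares regression line of `y` on `x` is reported alongside for
#' scatterplot annotation. No multiple-testing correction is applied.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"auto"` (normality-gated, default), `"pearson"` or
#'   `"spearman"`.
#' @param alpha significance level for the normality gate.
#' @return one-row data.frame of class `correlation_result`: `method`,
#'   `rho`, `p_value`, `n`, `slope`, `intercept`.
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman"),
                      alpha = 0.05) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the series")
  if (method == "auto") {
    # below the normality test's minimum sample size the rank method is the
    # safe default
    normal <- n >= 8L && isTRUE(test_normality(x, alpha)) &&
      isTRUE(test_normality(y, alpha))
    method <- if (normal) "pearson" else "spearman"
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE))
  fit <- stats::lm.fit(cbind(1, x), y)
  out <- data.frame(method = method, rho = unname(ct$estimate),
                    p_value = ct$p.value, n = n,
                    slope = fit$coefficients[2],
                    intercept = fit$coefficients[1],
                    row.names = NULL)
  class(out) <- c("correlation_result", class(out))
  out
}

#' Correlation table for a set of named comparisons
#'
#' @param pairs named list; each element is a list/pair `(x, y)`.
#' @param ... passed to [correlate()].
#' @return data.frame with one row per comparison (`comparison`, `method`,
#'   `rho`, `p_value`, `n`, `slope`, `intercept`), suitable for CSV export.
#' @export
correlation_table <- function(pairs, ...) {
  rows <- lapply(names(pairs), function(nm) {
    r <- correlate(pairs[[nm]][[1]], pairs[[nm]][[2]], ...)
    cbind(comparison = nm, as.data.frame(r))
  })
  do.call(rbind, rows)
}
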