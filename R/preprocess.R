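#' Composite a daily series into 8-day bins
#'
#' Averages available daily values within consecutive 8-day bins aligned to
#' the series anchor, the native resolution of level-3 ocean-colour products
#' (46 bins per year; the final bin of a year absorbs the residual days).
#' Bins with no valid observation are `NA`.
#'
#' @param daily a daily [regional_series()] or numeric vector.
#' @param bin_days bin length in days.
#' @return an 8-day [regional_series()].
#' @export
composite_to_8day <- function(daily, bin_days = 8L) {
  if (inherits(daily, "regional_series") && daily$resolution != "daily")
    stop("composite_to_8day() expects a daily series")
  v <- series_values(daily)
  bin <- (seq_along(v) - 1L) %/% bin_days
  means <- tapply(v, bin, function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  regional_series(as.numeric(means), resolution = "8day",
                  units = if (inherits(daily, "regional_series")) daily$units else "",
                  start_anchor = if (inherits(daily, "regional_series"))
                    daily$start_anchor else NULL)
}

#' Aggregate an 8-day series to pseudo-monthly means
#'
#' Averages the 46 8-day periods of each bloom year into 12 equal-duration
#' month-scale bins (fixed boundaries at `round(46 * (0:12) / 12)`), the
#' resolution used for monthly anomaly comparisons against mixed-layer depth.
#'
#' @param series an 8-day [regional_series()] or numeric vector.
#' @param periods_per_year periods per year (46).
#' @return a monthly [regional_series()], 12 values per year.
#' @export
composite_to_monthly <- function(series, periods_per_year = 46L) {
  v <- series_values(series)
  n_years <- length(v) %/% periods_per_year
  if (n_years < 1L) stop("series shorter than one year")
  edges <- round(periods_per_year * (0:12) / 12)
  out <- numeric(0)
  for (y in seq_len(n_years)) {
    yr <- v[((y - 1L) * periods_per_year + 1L):(y * periods_per_year)]
    out <- c(out, vapply(seq_len(12), function(m) {
      x <- yr[(edges[m] + 1L):edges[m + 1L]]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1)))
  }
  regional_series(out, resolution = "monthly",
                  units = if (inherits(series, "regional_series")) series$units else "")
}

#' Spatially average a gridded field into a regional series
#'
#' Per-time-step mean over unmasked pixels, optionally excluding pixels
#' flagged in `exclude_mask` (e.g. a coastal shallow-water mask). Time steps
#' with no valid pixel become `NA`.
#'
#' @param field a [gridded_field()].
#' @param exclude_mask optional logical `[lat, lon]` matrix, `TRUE` = drop.
#' @return a [regional_series()] at the field's resolution.
#' @export
spatial_average <- function(field, exclude_mask = NULL) {
  stopifnot(inherits(field, "gridded_field"))
  d <- dim(field$values)
  v <- field$values
  if (!is.null(exclude_mask)) {
    if (!identical(dim(exclude_mask), d[2:3]))
      stop("exclude_mask must be a [lat, lon] matrix matching the field")
    if (all(exclude_mask)) stop("all pixels excluded")
    v[, exclude_mask] <- NA_real_
  }
  m <- apply(v, 1, function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  regional_series(m, resolution = "8day", units = field$units)
}

#' Flag outliers by robust deviation from the median
#'
#' A reproducible surrogate for manual inspection of satellite retrievals:
#' points further than `k` scaled median absolute deviations from the series
#' median are flagged. Flagged points are normally set to missing and
#' gap-filled downstream. For strongly seasonal records pass
#' `periods_per_year`: the rule is then applied to deviations from the
#' per-period median seasonal cycle (a robust climatology that a spike
#' cannot contaminate), so the winter bloom itself is never mistaken for a
#' spike; [run_pipeline()] uses this seasonal form.
#'
#' @param series a [regional_series()] or numeric vector, length >= 12.
#' @param k deviation multiplier (default 5).
#' @param periods_per_year when given, deviations are measured from the
#'   per-period multi-year median rather than the series median.
#' @return logical vector, `TRUE` = outlier.
#' @export
flag_outliers <- function(series, k = 5, periods_per_year = NULL) {
  v <- series_values(series)
  if (sum(!is.na(v)) < 12L) stop("need at least 12 observed values")
  if (!is.null(periods_per_year)) {
    period <- ((seq_along(v) - 1L) %% periods_per_year) + 1L
    clim <- tapply(v, period, stats::median, na.rm = TRUE)
    v <- v - as.numeric(clim[period])
  }
  med <- stats::median(v, na.rm = TRUE)
  s <- stats::mad(v, na.rm = TRUE)
  if (s == 0) {
    warning("zero MAD; no outliers flagged")
    return(rep(FALSE, length(v)))
  }
  flags <- abs(v - med) > k * s
  flags[is.na(flags)] <- FALSE
  flags
}

# Smooth in-painting: fix observed values and choose the missing ones to
# minimise the summed squared second difference of the full series. Interior
# gaps are filled smoothly; leading/trailing gaps continue the local trend
# (the minimiser drives their second differences to zero).
fill_least_squares <- function(v) {
  n <- length(v)
  miss <- which(is.na(v))
  if (length(miss) == 0L) return(v)
  if (n < 3L) stop("series too short to in-paint")
  obs <- which(!is.na(v))
  # rows of the second-difference operator touching at least one unknown
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  Du <- D[, miss, drop = FALSE]
  Do <- D[, obs, drop = FALSE]
  A <- Matrix::crossprod(Du)
  b <- -Matrix::crossprod(Du, Do %*% v[obs])
  x <- tryCatch(as.numeric(Matrix::solve(A, b)),
                error = function(e) stop("gap pattern leaves the smoothing ",
                                         "system singular: ", conditionMessage(e)))
  v[miss] <- x
  v
}

fill_climatology <- function(v, periods_per_year) {
  n <- length(v)
  period <- ((seq_len(n) - 1L) %% periods_per_year) + 1L
  clim <- tapply(v, period, mean, na.rm = TRUE)
  if (anyNA(clim) || any(is.nan(clim)))
    stop("some periods have no observation in any year; cannot fill by climatology")
  miss <- is.na(v)
  v[miss] <- clim[period[miss]]
  v
}

#' Fill missing values in a regional series
#'
#' Two interchangeable strategies: `"least-squares"` in-paints missing points
#' by minimising the squared second difference of the completed series
#' (smooth interpolation that also extrapolates endpoints along the local
#' trend); `"climatology"` substitutes the multi-year mean of each 8-day
#' period. Complete series are returned unchanged by either method.
#'
#' @param series a [regional_series()] or numeric vector with `NA` gaps.
#' @param method `"least-squares"` (default) or `"climatology"`.
#' @param periods_per_year periods per year, used by the climatology method.
#' @return a gap-free series of the same class as the input.
#' @export
fill_gaps <- function(series, method = c("least-squares", "climatology"),
                      periods_per_year = 46L) {
  method <- match.arg(method)
  v <- series_values(series)
  if (all(is.na(v))) stop("series is entirely missing")
  if (mean(is.na(v)) > 0.5)
    stop("more than 50% of the series is missing; refusing to fill")
  filled <- switch(method,
                   "least-squares" = fill_least_squares(v),
                   "climatology" = fill_climatology(v, periods_per_year))
  if (inherits(series, "regional_series")) {
    series$values <- filled
    series
  } else filled
}

#' Compute anomalies of a regional series
#'
#' `"overall-mean"` subtracts the grand mean of the series (so anomalies sum
#' to zero); `"climatological"` subtracts each 8-day period's multi-year mean
#' (so a pure seasonal cycle maps to zero).
#'
#' @param series a gap-filled [regional_series()] or numeric vector.
#' @param baseline_kind `"overall-mean"` or `"climatological"`.
#' @param periods_per_year periods per year for the climatological baseline.
#' @return numeric anomaly vector with attributes `baseline_kind` and
#'   `standardised` (class `anomaly_series`).
#' @export
compute_anomalies <- function(series,
                              baseline_kind = c("overall-mean", "climatological"),
                              periods_per_year = 46L) {
  baseline_kind <- match.arg(baseline_kind)
  v <- series_values(series)
  a <- if (baseline_kind == "overall-mean") {
    v - mean(v, na.rm = TRUE)
  } else {
    period <- ((seq_along(v) - 1L) %% periods_per_year) + 1L
    clim <- tapply(v, period, mean, na.rm = TRUE)
    v - as.numeric(clim[period])
  }
  structure(a, baseline_kind = baseline_kind, standardised = FALSE,
            class = "anomaly_series")
}

#' Standardise an anomaly series
#'
#' Divides by the anomaly standard deviation so series in different units can
#' share an axis; the result is dimensionless with unit variance.
#'
#' @param anoms an `anomaly_series` (or numeric anomaly vector).
#' @return standardised `anomaly_series`.
#' @export
standardise <- function(anoms) {
  s <- stats::sd(anoms, na.rm = TRUE)
  if (!is.finite(s) || s == 0) stop("zero-variance anomalies cannot be standardised")
  structure(as.numeric(anoms) / s,
            baseline_kind = attr(anoms, "baseline_kind"),
            standardised = TRUE, class = "anomaly_series")
}

#' Named analysis windows on the 46-period bloom year
#'
#' Fixed period-index ranges (1-based; period 1 begins in mid-September) for
#' the windows used throughout the analysis: the general bloom peak
#' (late January to mid-March), winter (October to April), the initiation
#' window (October to December) and the termination window (February to
#' April).
#'
#' @return named list of integer period-index vectors.
#' @export
analysis_windows <- function() {
  list(bloom_peak = 17:23,
       winter = 3:29,
       initiation = 3:14,
       termination = 18:29)
}

#' Per-bloom-year average of a window of 8-day periods
#'
#' @param series an 8-day [regional_series()] or numeric vector whose first
#'   element is period 1 of bloom year 1.
#' @param window a window name understood by [analysis_windows()] or an
#'   integer vector of period indices in `1:periods_per_year`.
#' @param periods_per_year periods per bloom year.
#' @return numeric vector, one value per complete bloom year (`NA` when the
#'   window has no data in a year).
#' @export
window_average <- function(series, window = "bloom_peak",
                           periods_per_year = 46L) {
  v <- series_values(series)
  if (is.character(window)) {
    w <- analysis_windows()[[window]]
    if (is.null(w)) stop("unknown window '", window, "'; available: ",
                         paste(names(analysis_windows()), collapse = ", "))
    window <- w
  }
  window <- as.integer(window)
  if (any(window < 1L | window > periods_per_year))
    stop("window indices must lie in 1:periods_per_year")
  n_years <- length(v) %/% periods_per_year
  if (n_years < 1L) stop("series shorter than one bloom year")
  vapply(seq_len(n_years), function(y) {
    x <- v[(y - 1L) * periods_per_year + window]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1))
}
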