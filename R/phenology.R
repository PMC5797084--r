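#' Bloom threshold from a multi-year chlorophyll series
#'
#' The threshold criterion is the median of the whole multi-year series
#' elevated by a relative fraction (default 15%, i.e. `median * 1.15`),
#' computed once on the full record rather than per year. A bloom is the
#' sustained exceedance of this concentration.
#'
#' @param full_series gap-filled multi-year [regional_series()] or numeric
#'   vector of chlorophyll-a (mg m-3).
#' @param fraction relative elevation above the median (default 0.15).
#' @return threshold concentration (mg m-3).
#' @export
compute_threshold <- function(full_series, fraction = 0.15) {
  v <- series_values(full_series)
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("empty series")
  stats::median(v) * (1 + fraction)
}

#' Split a series into consecutive bloom-year windows
#'
#' Bloom years are consecutive 46-period windows anchored at the series start
#' (mid-September by convention, so the winter bloom is never split). A
#' partial trailing window is dropped with a warning.
#'
#' @param series [regional_series()] or numeric vector at 8-day resolution.
#' @param periods_per_year periods per bloom year.
#' @return data.frame with columns `year`, `start`, `end` (1-based indices).
#' @export
split_bloom_years <- function(series, periods_per_year = 46L) {
  n <- length(series_values(series))
  n_years <- n %/% periods_per_year
  if (n_years == 0L) stop("series shorter than one bloom year")
  rem <- n - n_years * periods_per_year
  if (rem > 0L)
    warning(sprintf("dropping %d trailing periods (partial bloom year)", rem))
  data.frame(year = seq_len(n_years),
             start = (seq_len(n_years) - 1L) * periods_per_year + 1L,
             end = seq_len(n_years) * periods_per_year)
}

#' Detect bloom timing within one bloom year
#'
#' The threshold-criterion / cumulative-sum method. Anomalies relative to the
#' threshold are accumulated; the gradient of the cumulative sum switches
#' sign exactly where the series crosses the threshold, and those transition
#' points define the phenology: initiation is the first period of the
#' above-threshold episode that contains the annual chlorophyll maximum (the
#' bloom peak), termination is the first period after the peak in which the
#' gradient turns negative (first fall below threshold), and duration is the
#' number of periods from initiation up to (excluding) termination. When the
#' series never exceeds the threshold, or the selected episode is shorter
#' than `min_duration`, the year is flagged `no_bloom` and the timing fields
#' are `NA`.
#'
#' Ties for the maximum resolve to the earliest period. If the episode is
#' still above threshold at the end of the window, termination is reported as
#' one past the final period (right-censored).
#'
#' @param year_series numeric vector of gap-filled chlorophyll for one bloom
#'   year (no `NA`).
#' @param threshold concentration from [compute_threshold()].
#' @param min_duration minimum above-threshold episode length, in periods,
#'   to declare a bloom (default 2).
#' @return one-row data.frame: `initiation`, `peak`, `termination`,
#'   `duration` (8-day period indices/counts), `peak_chl`, `no_bloom`.
#' @export
detect_bloom <- function(year_series, threshold, min_duration = 2L) {
  v <- as.numeric(series_values(year_series))
  if (anyNA(v)) stop("year series contains NA; gap-fill first")
  no_bloom <- data.frame(initiation = NA_integer_, peak = NA_integer_,
                         termination = NA_integer_, duration = NA_integer_,
                         peak_chl = NA_real_, no_bloom = TRUE)
  anom <- v - threshold
  csum <- cumsum(anom)
  grad <- diff(c(0, csum))        # gradient of cumulative sum == anomaly
  above <- grad > 0
  if (!any(above)) return(no_bloom)
  r <- rle(above)
  ep_end <- cumsum(r$lengths)
  ep_start <- ep_end - r$lengths + 1L
  ep_start <- ep_start[r$values]
  ep_end <- ep_end[r$values]
  peak <- which.max(v)            # earliest period on ties
  sel <- which(ep_start <= peak & ep_end >= peak)
  init <- ep_start[sel]
  term <- ep_end[sel] + 1L        # first period back below threshold
  if (term - init < min_duration) return(no_bloom)
  data.frame(initiation = init, peak = peak, termination = term,
             duration = term - init, peak_chl = v[peak], no_bloom = FALSE)
}

#' Per-year phenology indices of a multi-year regional series
#'
#' Splits the series into bloom years, computes one whole-record threshold,
#' and runs [detect_bloom()] on each year.
#'
#' @param series gap-filled multi-year 8-day [regional_series()] or vector.
#' @param threshold_fraction relative threshold elevation (default 0.15).
#' @param min_duration minimum episode length to declare a bloom.
#' @param periods_per_year periods per bloom year.
#' @param threshold optional pre-computed threshold overriding
#'   `threshold_fraction`.
#' @return data.frame, one row per bloom year, columns of [detect_bloom()]
#'   plus `year`; the threshold used is attached as attribute `threshold`.
#' @export
detect_phenology <- function(series, threshold_fraction = 0.15,
                             min_duration = 2L, periods_per_year = 46L,
                             threshold = NULL) {
  v <- series_values(series)
  years <- split_bloom_years(v, periods_per_year)
  if (is.null(threshold))
    threshold <- compute_threshold(v[seq_len(nrow(years) * periods_per_year)],
                                   threshold_fraction)
  rows <- lapply(seq_len(nrow(years)), function(y) {
    res <- detect_bloom(v[years$start[y]:years$end[y]], threshold,
                        min_duration)
    cbind(year = y, res)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' Annual anomalies of phenology indices
#'
#' For each timing index, anomaly = value minus the mean over all years in
#' which a bloom was detected; years flagged `no_bloom` are excluded from
#' both the baseline and the output (mirroring the exclusion of years with
#' no detectable bloom from interannual statistics).
#'
#' @param indices data.frame from [detect_phenology()].
#' @return data.frame with `year` and anomaly columns `initiation`, `peak`,
#'   `termination`, `duration` (units: 8-day periods).
#' @export
phenology_anomalies <- function(indices) {
  ok <- !indices$no_bloom
  if (sum(ok) < 2L) stop("need at least 2 years with a detected bloom")
  cols <- c("initiation", "peak", "termination", "duration")
  out <- data.frame(year = indices$year[ok])
  for (cl in cols)
    out[[cl]] <- indices[[cl]][ok] - mean(indices[[cl]][ok])
  out
}

#' Pixel-by-pixel bloom phenology maps
#'
#' Applies the threshold-criterion method independently at every pixel of a
#' gridded chlorophyll field: coastal pixels (bathymetry shallower than
#' `depth_cutoff`, where optical complexity degrades retrievals) are masked;
#' each remaining pixel is gap-filled, given its own whole-record threshold,
#' and scanned year by year with [detect_bloom()]. Pixels missing more than
#' `max_missing` of their observations are masked and counted.
#'
#' @param field chlorophyll [gridded_field()] `[time, lat, lon]`.
#' @param bathymetry depth (m, positive down) as a `[lat, lon]` matrix or a
#'   time-invariant [gridded_field()] co-registered with `field`.
#' @param depth_cutoff coastal depth cutoff in metres (default 100).
#' @param threshold_fraction,min_duration,periods_per_year as in
#'   [detect_phenology()].
#' @param max_missing maximum tolerated missing fraction per pixel.
#' @param fill_method gap-fill method passed to [fill_gaps()].
#' @return object of class `phenology_maps`: arrays `[lat, lon, year]` for
#'   `initiation`, `peak`, `termination`, `duration`, logical `no_bloom`,
#'   plus `coastal_mask` and `excluded_mask` `[lat, lon]` layers and the
#'   count of pixels dropped for missing data.
#' @export
phenology_per_pixel <- function(field, bathymetry, depth_cutoff = 100,
                                threshold_fraction = 0.15, min_duration = 2L,
                                periods_per_year = 46L, max_missing = 0.5,
                                fill_method = "least-squares") {
  stopifnot(inherits(field, "gridded_field"))
  depth <- if (inherits(bathymetry, "gridded_field")) {
    bathymetry$values[1, , ]
  } else as.matrix(bathymetry)
  d <- dim(field$values)
  if (!identical(dim(depth), d[2:3]))
    stop("bathymetry is not co-registered with the chlorophyll field")
  coastal <- depth < depth_cutoff
  n_years <- d[1] %/% periods_per_year
  if (n_years == 0L) stop("field shorter than one bloom year")
  dims <- c(d[2], d[3], n_years)
  maps <- list(initiation = array(NA_real_, dims),
               peak = array(NA_real_, dims),
               termination = array(NA_real_, dims),
               duration = array(NA_real_, dims),
               no_bloom = array(NA, dims))
  excluded <- matrix(FALSE, d[2], d[3])
  n_used <- d[1] - d[1] %% periods_per_year
  for (i in seq_len(d[2])) {
    for (j in seq_len(d[3])) {
      if (coastal[i, j]) next
      px <- field$values[seq_len(n_used), i, j]
      if (mean(is.na(px)) > max_missing) {
        excluded[i, j] <- TRUE
        next
      }
      px <- fill_gaps(px, method = fill_method,
                      periods_per_year = periods_per_year)
      idx <- suppressWarnings(
        detect_phenology(px, threshold_fraction = threshold_fraction,
                         min_duration = min_duration,
                         periods_per_year = periods_per_year))
      maps$initiation[i, j, ] <- idx$initiation
      maps$peak[i, j, ] <- idx$peak
      maps$termination[i, j, ] <- idx$termination
      maps$duration[i, j, ] <- idx$duration
      maps$no_bloom[i, j, ] <- idx$no_bloom
    }
  }
  n_excluded <- sum(excluded)
  if (n_excluded > 0)
    message(sprintf("phenology_per_pixel: %d pixel(s) dropped for >%.0f%% missing data",
                    n_excluded, 100 * max_missing))
  structure(list(initiation = maps$initiation, peak = maps$peak,
                 termination = maps$termination, duration = maps$duration,
                 no_bloom = maps$no_bloom, coastal_mask = coastal,
                 excluded_mask = excluded, n_excluded = n_excluded,
                 lat = field$lat, lon = field$lon, units = "8-day periods"),
            class = "phenology_maps")
}

#' @method print phenology_maps
#' @export
print.phenology_maps <- function(x, ...) {
  d <- dim(x$initiation)
  cat(sprintf("<phenology_maps> %d lat x %d lon x %d bloom years; %d coastal, %d excluded pixels\n",
              d[1], d[2], d[3], sum(x$coastal_mask), x$n_excluded))
  invisible(x)
}
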