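#' Classify bloom years as warm, cold or neutral
#'
#' Years are classified from their SST anomaly averaged over the bloom-peak
#' window: warm when the anomaly is at least `+neutral_band`, cold when at
#' most `-neutral_band`, otherwise neutral (near-average years are excluded
#' from composites). The band is a free parameter; 0.25 degC gives a
#' two-sided exclusion of near-average years.
#'
#' @param sst_peak_anoms per-year SST anomalies (degC) over the bloom-peak
#'   window, e.g. from [aggregate_driver()] with `window = "bloom_peak"`.
#' @param neutral_band half-width of the neutral band in degC.
#' @return data.frame with `year`, `class` (factor warm/cold/neutral) and
#'   `peak_sst_anomaly`.
#' @export
classify_years <- function(sst_peak_anoms, neutral_band = 0.25) {
  if (neutral_band <= 0) stop("neutral_band must be positive")
  cls <- ifelse(sst_peak_anoms >= neutral_band, "warm",
                ifelse(sst_peak_anoms <= -neutral_band, "cold", "neutral"))
  cls[is.na(sst_peak_anoms)] <- "neutral"
  if (all(cls == "neutral"))
    stop("all years classified neutral; consider a smaller neutral_band")
  data.frame(year = seq_along(sst_peak_anoms),
             class = factor(cls, levels = c("warm", "cold", "neutral")),
             peak_sst_anomaly = sst_peak_anoms)
}

#' Warm-minus-cold composite difference maps of phenology indices
#'
#' For each pixel and each index (initiation, peak, termination, duration),
#' the mean over warm years minus the mean over cold years, using at each
#' pixel only the years in which that pixel has a detected bloom (no-bloom
#' years are dropped from the pixel's composite rather than propagating
#' `NA`). Pixels with no valid year on either side, coastal pixels, and
#' pixels excluded for missing data are `NA`. Sign convention: a positive
#' initiation difference means a later bloom start under warm conditions.
#'
#' @param maps a `phenology_maps` object from [phenology_per_pixel()].
#' @param classes data.frame from [classify_years()] (or a factor/character
#'   vector of classes per year).
#' @return object of class `phenology_composite`: matrices `[lat, lon]` named
#'   `initiation_diff`, `peak_diff`, `termination_diff`, `duration_diff`
#'   (units: 8-day periods), plus the warm/cold year index sets.
#' @export
composite_difference <- function(maps, classes) {
  stopifnot(inherits(maps, "phenology_maps"))
  cls <- if (is.data.frame(classes)) as.character(classes$class) else as.character(classes)
  n_years <- dim(maps$initiation)[3]
  if (length(cls) != n_years)
    stop("classes length must equal the number of bloom years in the maps")
  warm <- which(cls == "warm")
  cold <- which(cls == "cold")
  if (length(warm) < 1L || length(cold) < 1L)
    stop("need at least one warm and one cold year")
  comp_one <- function(arr) {
    ok <- !maps$no_bloom          # detected-bloom indicator per [lat,lon,year]
    ok[is.na(ok)] <- FALSE
    vals <- arr
    vals[!ok] <- NA_real_
    mean_over <- function(yrs) {
      apply(vals[, , yrs, drop = FALSE], c(1, 2), function(x) {
        if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
      })
    }
    mean_over(warm) - mean_over(cold)
  }
  out <- list(initiation_diff = comp_one(maps$initiation),
              peak_diff = comp_one(maps$peak),
              termination_diff = comp_one(maps$termination),
              duration_diff = comp_one(maps$duration))
  if (all(vapply(out, function(m) all(is.na(m)), logical(1))))
    stop("no pixel has a detected bloom in both a warm and a cold year")
  structure(c(out, list(warm_years = warm, cold_years = cold,
                        lat = maps$lat, lon = maps$lon,
                        units = "8-day periods")),
            class = "phenology_composite")
}

#' @method print phenology_composite
#' @export
print.phenology_composite <- function(x, ...) {
  cat(sprintf("<phenology_composite> warm years {%s} minus cold years {%s}\n",
              paste(x$warm_years, collapse = ","),
              paste(x$cold_years, collapse = ",")))
  for (nm in c("initiation_diff", "termination_diff", "duration_diff"))
    cat(sprintf("  %-17s mean %+.2f periods (open-ocean pixels)\n", nm,
                mean(x[[nm]], na.rm = TRUE)))
  invisible(x)
}
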