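#' Regional time series
#'
#' A regularly spaced scalar time series, typically the area average of a
#' gridded geophysical variable over a study region. The native resolution of
#' the phenology analysis is the 8-day composite grid (46 periods per year,
#' anchored in mid-September so a winter bloom is never split across annual
#' windows); daily and monthly series are supported for compositing and
#' monthly-anomaly work.
#'
#' @param values numeric vector; `NA` marks missing observations.
#' @param resolution one of `"8day"`, `"daily"`, `"monthly"`.
#' @param units unit string, e.g. `"mg m-3"`, `"degC"`, `"W m-2"`.
#' @param start_anchor optional ISO date string recording the calendar date of
#'   the first element; the analysis itself runs on integer period indices.
#' @param periods_per_year periods per bloom year at 8-day resolution.
#' @return an object of class `regional_series`.
#' @export
regional_series <- function(values, resolution = c("8day", "daily", "monthly"),
                            units = "", start_anchor = NULL,
                            periods_per_year = 46L) {
  resolution <- match.arg(resolution)
  if (!is.numeric(values)) stop("`values` must be numeric")
  structure(
    list(values = as.numeric(values), resolution = resolution, units = units,
         start_anchor = start_anchor,
         periods_per_year = as.integer(periods_per_year)),
    class = "regional_series")
}

#' @method print regional_series
#' @export
print.regional_series <- function(x, ...) {
  cat(sprintf("<regional_series> %d values (%s, %s), %d missing\n",
              length(x$values), x$resolution, x$units, sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.regional_series <- function(x) length(x$values)

series_values <- function(x) {
  if (inherits(x, "regional_series")) x$values else as.numeric(x)
}

#' Gridded geophysical field
#'
#' One variable on a regular latitude-longitude grid through time. Missing
#' observations are carried both as `NA` in `values` and as `TRUE` in `mask`.
#'
#' @param values 3-D numeric array `[time, lat, lon]`.
#' @param lat,lon numeric coordinate vectors of pixel centres (degrees),
#'   strictly monotone.
#' @param time integer or numeric time axis (8-day period index by default);
#'   must be strictly increasing and evenly spaced.
#' @param units unit string.
#' @param variable variable name used in file I/O (e.g. `"chlor_a"`).
#' @return an object of class `gridded_field`.
#' @export
gridded_field <- function(values, lat, lon, time = seq_len(dim(values)[1]),
                          units = "", variable = "value") {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array [time, lat, lon]")
  d <- dim(values)
  if (d[1] != length(time) || d[2] != length(lat) || d[3] != length(lon))
    stop("array dimensions do not match time/lat/lon lengths")
  if (length(time) > 1) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("time axis must be strictly increasing")
    if (max(dt) - min(dt) > 1e-8 * max(abs(dt)))
      stop("time axis must be evenly spaced")
  }
  structure(
    list(values = values, lat = as.numeric(lat), lon = as.numeric(lon),
         time = time, units = units, variable = variable,
         mask = is.na(values)),
    class = "gridded_field")
}

#' @method print gridded_field
#' @export
print.gridded_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<gridded_field> %s [%s]: %d time x %d lat x %d lon, %.1f%% missing\n",
              x$variable, x$units, d[1], d[2], d[3],
              100 * mean(x$mask)))
  invisible(x)
}

#' Geographic bounding box
#'
#' Rectangular region in degrees; subsetting keeps pixels whose centres fall
#' in the half-open intervals `[lon_min, lon_max)` and `[lat_min, lat_max)` so
#' adjacent boxes never double-count a pixel.
#'
#' @param lon_min,lon_max,lat_min,lat_max box edges in degrees.
#' @return an object of class `region_box`.
#' @export
region_box <- function(lon_min, lon_max, lat_min, lat_max) {
  if (lon_min >= lon_max || lat_min >= lat_max)
    stop("box must satisfy lon_min < lon_max and lat_min < lat_max")
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max),
            class = "region_box")
}

#' Temperature profile time series
#'
#' Depth-resolved temperature through time, the input to mixed-layer-depth
#' estimation.
#'
#' @param temperature 2-D numeric matrix `[time, depth]` in degrees C.
#' @param depth_levels depths in metres, strictly increasing downward.
#' @param time time axis (8-day period index by default).
#' @return an object of class `temperature_profile_series`.
#' @export
temperature_profile_series <- function(temperature, depth_levels,
                                       time = seq_len(nrow(temperature))) {
  temperature <- as.matrix(temperature)
  if (ncol(temperature) != length(depth_levels))
    stop("ncol(temperature) must equal length(depth_levels)")
  if (nrow(temperature) != length(time))
    stop("nrow(temperature) must equal length(time)")
  if (any(diff(depth_levels) <= 0))
    stop("depth_levels must be strictly increasing")
  if (anyNA(temperature))
    stop("temperature profiles must not contain NA within the valid range")
  structure(list(temperature = temperature,
                 depth_levels = as.numeric(depth_levels), time = time),
            class = "temperature_profile_series")
}

#' @method print temperature_profile_series
#' @export
print.temperature_profile_series <- function(x, ...) {
  cat(sprintf("<temperature_profile_series> %d times x %d depth levels (%.0f-%.0f m)\n",
              nrow(x$temperature), length(x$depth_levels),
              min(x$depth_levels), max(x$depth_levels)))
  invisible(x)
}
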