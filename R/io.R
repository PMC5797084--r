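#' Write a gridded field to a long-format CSV file
#'
#' The on-disk format is plain text: a small header block of `#`-prefixed
#' key-value lines (variable name, units, coordinate vectors, time axis)
#' followed by one CSV row per `(time, lat, lon)` cell. Missing observations
#' are written as empty fields and restored to the mask on read. Round trips
#' preserve values, mask, units and coordinates to full double precision.
#'
#' @param field a [gridded_field()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gridded <- function(field, path) {
  stopifnot(inherits(field, "gridded_field"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(
    sprintf("# variable: %s", field$variable),
    sprintf("# units: %s", field$units),
    sprintf("# lat: %s", paste(format(field$lat, digits = 17), collapse = " ")),
    sprintf("# lon: %s", paste(format(field$lon, digits = 17), collapse = " ")),
    sprintf("# time: %s", paste(format(field$time, digits = 17), collapse = " ")))
  writeLines(hdr, con)
  d <- dim(field$values)
  idx <- expand.grid(t = seq_len(d[1]), i = seq_len(d[2]), j = seq_len(d[3]))
  df <- data.frame(time_index = idx$t, lat_index = idx$i, lon_index = idx$j)
  v <- as.vector(field$values)
  df[[field$variable]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_header_block <- function(path) {
  lines <- readLines(path, n = 64L)
  hdr <- grep("^#", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) out[[trimws(m[2])]] <- m[3]
  }
  out
}

#' Read a gridded field from a long-format CSV file
#'
#' @param path file written by [write_gridded()].
#' @param variable_name variable (value column) to read; if the file does not
#'   contain it, the error names the variables that are available.
#' @return a [gridded_field()].
#' @export
read_gridded <- function(path, variable_name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- read_header_block(path)
  for (key in c("lat", "lon", "time"))
    if (is.null(hdr[[key]])) stop("file lacks '# ", key, ":' header: ", path)
  lat <- as.numeric(strsplit(trimws(hdr$lat), "\\s+")[[1]])
  lon <- as.numeric(strsplit(trimws(hdr$lon), "\\s+")[[1]])
  time <- as.numeric(strsplit(trimws(hdr$time), "\\s+")[[1]])
  df <- utils::read.csv(path, comment.char = "#")
  value_cols <- setdiff(names(df), c("time_index", "lat_index", "lon_index"))
  if (is.null(variable_name)) {
    if (length(value_cols) != 1L)
      stop("file holds several variables (", paste(value_cols, collapse = ", "),
           "); pass `variable_name`")
    variable_name <- value_cols
  }
  if (!variable_name %in% value_cols)
    stop("variable '", variable_name, "' not found; available: ",
         paste(value_cols, collapse = ", "))
  vals <- array(NA_real_, dim = c(length(time), length(lat), length(lon)))
  vals[cbind(df$time_index, df$lat_index, df$lon_index)] <- df[[variable_name]]
  gridded_field(vals, lat = lat, lon = lon, time = time,
                units = if (is.null(hdr$units)) "" else hdr$units,
                variable = variable_name)
}

#' Write a regional series as two-column CSV
#'
#' Columns are `period` (integer index from the series anchor) and `value`;
#' resolution, units and anchor are recorded in `#` header lines.
#'
#' @param series a [regional_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regional_series <- function(series, path) {
  stopifnot(inherits(series, "regional_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# resolution: %s", series$resolution),
               sprintf("# units: %s", series$units),
               sprintf("# start_anchor: %s",
                       if (is.null(series$start_anchor)) "" else series$start_anchor)),
             con)
  v <- series$values
  utils::write.csv(
    data.frame(period = seq_along(v),
               value = ifelse(is.na(v), "", sprintf("%.17g", v))),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a regional series written by [write_regional_series()]
#'
#' @param path file path.
#' @return a [regional_series()].
#' @export
read_regional_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- read_header_block(path)
  df <- utils::read.csv(path, comment.char = "#")
  anchor <- hdr$start_anchor
  if (!is.null(anchor) && !nzchar(trimws(anchor))) anchor <- NULL
  regional_series(df$value,
                  resolution = if (is.null(hdr$resolution)) "8day" else hdr$resolution,
                  units = if (is.null(hdr$units)) "" else hdr$units,
                  start_anchor = anchor)
}

#' Subset a gridded field to a geographic box
#'
#' Keeps pixels whose centres lie in the half-open box
#' `[lon_min, lon_max) x [lat_min, lat_max)`; coordinates are preserved.
#'
#' @param field a [gridded_field()].
#' @param box a [region_box()].
#' @return the subset [gridded_field()].
#' @export
subset_region <- function(field, box) {
  stopifnot(inherits(field, "gridded_field"), inherits(box, "region_box"))
  keep_lat <- field$lat >= box$lat_min & field$lat < box$lat_max
  keep_lon <- field$lon >= box$lon_min & field$lon < box$lon_max
  if (!any(keep_lat) || !any(keep_lon))
    stop("box does not intersect the field's pixel centres")
  gridded_field(field$values[, keep_lat, keep_lon, drop = FALSE],
                lat = field$lat[keep_lat], lon = field$lon[keep_lon],
                time = field$time, units = field$units,
                variable = field$variable)
}

#' Write a temperature profile series as long-format CSV
#'
#' @param profiles a [temperature_profile_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "temperature_profile_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# depth_levels: %s",
                     paste(format(profiles$depth_levels, digits = 17),
                           collapse = " ")), con)
  idx <- expand.grid(t = seq_len(nrow(profiles$temperature)),
                     z = seq_along(profiles$depth_levels))
  utils::write.csv(
    data.frame(time_index = idx$t, depth_index = idx$z,
               temperature = sprintf("%.17g", as.vector(profiles$temperature))),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a temperature profile series written by [write_profiles()]
#'
#' @param path file path.
#' @return a [temperature_profile_series()].
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- read_header_block(path)
  if (is.null(hdr$depth_levels)) stop("file lacks '# depth_levels:' header")
  depths <- as.numeric(strsplit(trimws(hdr$depth_levels), "\\s+")[[1]])
  df <- utils::read.csv(path, comment.char = "#")
  temp <- matrix(NA_real_, nrow = max(df$time_index), ncol = length(depths))
  temp[cbind(df$time_index, df$depth_index)] <- df$temperature
  temperature_profile_series(temp, depth_levels = depths)
}
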