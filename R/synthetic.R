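#' Configuration for the synthetic study generator
#'
#' Defines the statistical structure of a synthetic multi-year study: an
#' annual winter chlorophyll bloom anti-phased with a sinusoidal SST cycle,
#' interannual warm years that delay initiation, advance termination, damp
#' bloom amplitude and raise SST, a winter-deepening mixed layer that
#' shoals in warm years, net air-sea heat loss that weakens in warm years,
#' spatial heterogeneity (a later-blooming southeast block), coastal shallow
#' pixels, and missing-completely-at-random chlorophyll observations.
#'
#' The time axis is an integer 8-day period index with 46 periods per bloom
#' year, period 1 anchored in mid-September. The default bloom occupies
#' periods 10-25 above threshold (initiation period 10, early December;
#' termination period 26, early April; duration 16 periods, about four
#' months). All planted timings are exact positions on this grid, so a
#' noiseless run is recoverable exactly.
#'
#' @param n_years number of bloom years.
#' @param periods_per_year periods per bloom year (46 = 8-day grid).
#' @param grid_shape `c(n_lat, n_lon)`, at least 4 x 4.
#' @param chl_baseline minimum (summer) out-of-bloom chlorophyll (mg m-3).
#' @param chl_seasonal_amplitude gentle seasonal modulation of the baseline,
#'   peaking in winter (mg m-3); gives the climatology the smooth,
#'   SST-anti-phased annual cycle of real oligotrophic records rather than a
#'   flat summer floor.
#' @param bloom_amplitude bloom peak elevation above baseline (mg m-3).
#' @param bloom_center_period centre of the bloom episode (period index).
#' @param bloom_width half-width: the above-threshold episode runs from
#'   `bloom_center_period - bloom_width` (initiation) to
#'   `bloom_center_period + bloom_width - 1`, with termination (first period
#'   back at baseline) at `bloom_center_period + bloom_width`.
#' @param bloom_edge_fraction fraction of the (scaled) amplitude carried by
#'   the first and last episode periods; keeps the threshold crossing steep.
#' @param sst_mean,sst_amplitude,sst_phase annual SST cycle (degC; minimum at
#'   `sst_phase`, default the bloom centre, so SST is anti-phased with the
#'   bloom).
#' @param warm_years integer indices of warm bloom years.
#' @param warm_sst_offset SST elevation in warm years (degC).
#' @param warm_initiation_delay periods by which warm-year initiation is late.
#' @param warm_termination_advance periods by which warm-year termination is
#'   early.
#' @param warm_amplitude_factor multiplicative bloom damping in warm years,
#'   in (0, 1].
#' @param southeast_delay extra periods added to both initiation and
#'   termination in the southeast grid block.
#' @param noise_sd_chl,noise_sd_sst,noise_sd_heatflux observation noise
#'   standard deviations (mg m-3, degC, W m-2).
#' @param missing_fraction fraction of chlorophyll observations masked at
#'   random, in `[0, 1)`.
#' @param coastal_fraction fraction of grid pixels assigned depth < 100 m.
#' @param mld_winter_max,mld_summer_min seasonal mixed-layer depth range (m).
#' @param warm_mld_factor fraction of the seasonal MLD range reached in warm
#'   winters (shallower mixing), in (0, 1].
#' @param heatflux_mean,heatflux_amplitude net air-sea heat flux cycle
#'   (W m-2; most negative, strongest heat loss, at the bloom centre).
#' @param warm_heatflux_offset flux added in warm years (weaker heat loss).
#' @param depth_max,depth_step temperature-profile depth grid (m).
#' @param thermocline_gradient temperature decrease below the mixed layer
#'   (degC per m).
#' @param seed integer RNG seed; every generator output is bit-reproducible
#'   given the seed.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_years = 18L, periods_per_year = 46L,
                             grid_shape = c(8L, 8L),
                             chl_baseline = 0.2, chl_seasonal_amplitude = 0.04,
                             bloom_amplitude = 0.3,
                             bloom_center_period = 18L, bloom_width = 8L,
                             bloom_edge_fraction = 0.25,
                             sst_mean = 25, sst_amplitude = 3,
                             sst_phase = bloom_center_period,
                             warm_years = c(2L, 9L, 13L, 14L, 16L, 17L, 18L),
                             warm_sst_offset = 1.2,
                             warm_initiation_delay = 2L,
                             warm_termination_advance = 4L,
                             warm_amplitude_factor = 0.7,
                             southeast_delay = 2L,
                             noise_sd_chl = 0.02, noise_sd_sst = 0.2,
                             noise_sd_heatflux = 10,
                             missing_fraction = 0.2, coastal_fraction = 0.15,
                             mld_winter_max = 200, mld_summer_min = 20,
                             warm_mld_factor = 0.5,
                             heatflux_mean = -20, heatflux_amplitude = 150,
                             warm_heatflux_offset = 40,
                             depth_max = 300, depth_step = 5,
                             thermocline_gradient = 0.05,
                             seed = 1L) {
  cfg <- as.list(environment())
  cfg$warm_years <- as.integer(warm_years[warm_years <= n_years])
  with(cfg, {
    if (n_years < 1L) stop("n_years must be >= 1")
    if (bloom_center_period < 1L || bloom_center_period > periods_per_year)
      stop("bloom_center_period must lie within the bloom year")
    if (bloom_width <= 0) stop("bloom_width must be positive")
    if (warm_amplitude_factor <= 0 || warm_amplitude_factor > 1)
      stop("warm_amplitude_factor must lie in (0, 1]")
    if (missing_fraction < 0 || missing_fraction >= 1)
      stop("missing_fraction must lie in [0, 1)")
    if (coastal_fraction < 0 || coastal_fraction >= 1)
      stop("coastal_fraction must lie in [0, 1)")
    if (mld_winter_max <= mld_summer_min || mld_summer_min <= 0)
      stop("need mld_winter_max > mld_summer_min > 0")
    init <- bloom_center_period - bloom_width
    term <- bloom_center_period + bloom_width
    if (init < 1L || term > periods_per_year)
      stop("bloom episode must fit inside the bloom year")
    warm_dur <- (term - warm_termination_advance) -
      (init + warm_initiation_delay)
    if (warm_dur < 1L)
      stop("planted warm-year bloom would be shorter than 1 period")
  })
  structure(cfg, class = "synthetic_config")
}

# planted per-year episode edges on the within-year period grid
planted_truth <- function(config, extra_delay = 0L) {
  init0 <- config$bloom_center_period - config$bloom_width + extra_delay
  term0 <- config$bloom_center_period + config$bloom_width + extra_delay
  warm <- seq_len(config$n_years) %in% config$warm_years
  data.frame(
    year = seq_len(config$n_years),
    initiation = ifelse(warm, init0 + config$warm_initiation_delay, init0),
    termination = ifelse(warm, term0 - config$warm_termination_advance, term0),
    warm = warm)
}

# flat-topped bump over one episode: ramps up over the first 30% of the
# episode, holds a stable plateau (the "general peak"), ramps down over the
# last 30%; edges carry edge_frac of the full height so threshold crossings
# are steep
bump_shape <- function(len, edge_frac) {
  if (len == 1L) return(1)
  u <- (seq_len(len) - 1) / (len - 1)
  r <- 0.3
  h <- ifelse(u < r, sin(pi / 2 * u / r)^2,
              ifelse(u > 1 - r, sin(pi / 2 * (1 - u) / r)^2, 1))
  edge_frac + (1 - edge_frac) * h
}

# noiseless chlorophyll for the full record given per-year episode edges:
# a gently winter-peaking baseline plus the flat-topped bloom bump
chl_signal <- function(config, truth) {
  P <- config$periods_per_year
  p <- rep(seq_len(P), config$n_years)
  v <- config$chl_baseline + config$chl_seasonal_amplitude *
    (1 + cos(2 * pi * (p - config$bloom_center_period) / P)) / 2
  for (y in seq_len(config$n_years)) {
    amp <- config$bloom_amplitude *
      if (truth$warm[y]) config$warm_amplitude_factor else 1
    span <- truth$initiation[y]:(truth$termination[y] - 1L)
    at <- (y - 1L) * P + span
    v[at] <- v[at] + amp * bump_shape(length(span), config$bloom_edge_fraction)
  }
  v
}

# annual cycles evaluated on the full record, with warm-year offsets
sst_signal <- function(config, truth) {
  P <- config$periods_per_year
  p <- rep(seq_len(P), config$n_years)
  base <- config$sst_mean -
    config$sst_amplitude * cos(2 * pi * (p - config$sst_phase) / P)
  base + rep(ifelse(truth$warm, config$warm_sst_offset, 0), each = P)
}

heatflux_signal <- function(config, truth) {
  P <- config$periods_per_year
  p <- rep(seq_len(P), config$n_years)
  base <- config$heatflux_mean -
    config$heatflux_amplitude * cos(2 * pi * (p - config$bloom_center_period) / P)
  base + rep(ifelse(truth$warm, config$warm_heatflux_offset, 0), each = P)
}

mld_signal <- function(config, truth) {
  P <- config$periods_per_year
  p <- rep(seq_len(P), config$n_years)
  winter_max <- ifelse(truth$warm,
                       config$mld_summer_min + config$warm_mld_factor *
                         (config$mld_winter_max - config$mld_summer_min),
                       config$mld_winter_max)
  wk <- rep(winter_max, each = P)
  config$mld_summer_min + (wk - config$mld_summer_min) *
    (1 + cos(2 * pi * (p - config$bloom_center_period) / P)) / 2
}

#' Generate synthetic regional series with planted phenology truth
#'
#' Produces area-average chlorophyll-a, SST and net air-sea heat-flux series
#' on the 8-day bloom-year grid. Chlorophyll is a flat-topped winter bloom
#' over a constant baseline (damped, late-starting and early-ending in warm
#' years) with Gaussian noise and missing-at-random gaps; SST is a sinusoid
#' anti-phased with the bloom, elevated in warm years; heat flux is most
#' negative (strongest heat loss) in winter and less negative in warm years.
#'
#' @param config a [synthetic_config()].
#' @return list: `chl`, `sst`, `heatflux` ([regional_series()]) and `truth`,
#'   a per-year data.frame of planted `initiation`, `termination`,
#'   `duration` (8-day periods, within-year 1-based) and `warm` flags.
#' @export
generate_regional_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  truth <- planted_truth(config)
  n <- config$n_years * config$periods_per_year
  chl <- chl_signal(config, truth) + stats::rnorm(n, 0, config$noise_sd_chl)
  chl <- pmax(chl, 0.001)          # concentrations stay positive
  if (config$missing_fraction > 0) {
    gaps <- sample.int(n, size = round(config$missing_fraction * n))
    chl[gaps] <- NA_real_
  }
  sst <- sst_signal(config, truth) + stats::rnorm(n, 0, config$noise_sd_sst)
  hf <- heatflux_signal(config, truth) +
    stats::rnorm(n, 0, config$noise_sd_heatflux)
  truth$duration <- truth$termination - truth$initiation
  list(chl = regional_series(chl, "8day", units = "mg m-3"),
       sst = regional_series(sst, "8day", units = "degC"),
       heatflux = regional_series(hf, "8day", units = "W m-2"),
       truth = truth)
}

#' Generate a synthetic gridded chlorophyll scene with planted truth maps
#'
#' Every pixel carries the regional bloom structure with independent noise; a
#' contiguous southeast block (southern rows, eastern columns) blooms
#' `southeast_delay` periods later; `coastal_fraction` of pixels are assigned
#' shallow (< 100 m) bathymetry; `missing_fraction` of the observations are
#' masked completely at random.
#'
#' @param config a [synthetic_config()]; `grid_shape` must be >= 4 x 4.
#' @return list: `chl` ([gridded_field()]), `bathymetry` (`[lat, lon]` depth
#'   matrix, m), `truth`, a list of `[lat, lon, year]` arrays (`initiation`,
#'   `termination`, `duration`), `se_block` logical map, and the per-year
#'   `warm` flags.
#' @export
generate_gridded_scene <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  nlat <- config$grid_shape[1]; nlon <- config$grid_shape[2]
  if (nlat < 4L || nlon < 4L)
    stop("grid too small: need at least 4 x 4 pixels for a southeast block and coastal pixels")
  set.seed(config$seed + 1L)
  P <- config$periods_per_year
  n <- config$n_years * P
  lat <- seq(25.5, 27.8, length.out = nlat)  # south = first rows
  lon <- seq(33, 37, length.out = nlon)      # east = last columns
  se_block <- matrix(FALSE, nlat, nlon)
  se_block[seq_len(floor(nlat / 2)), (nlon - floor(nlon / 2) + 1L):nlon] <- TRUE
  truth_main <- planted_truth(config)
  truth_se <- planted_truth(config, extra_delay = config$southeast_delay)
  sig_main <- chl_signal(config, truth_main)
  sig_se <- chl_signal(config, truth_se)
  vals <- array(NA_real_, dim = c(n, nlat, nlon))
  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      sig <- if (se_block[i, j]) sig_se else sig_main
      vals[, i, j] <- pmax(sig + stats::rnorm(n, 0, config$noise_sd_chl), 0.001)
    }
  }
  if (config$missing_fraction > 0) {
    ncell <- length(vals)
    vals[sample.int(ncell, size = round(config$missing_fraction * ncell))] <- NA_real_
  }
  npix <- nlat * nlon
  bathy <- matrix(500, nlat, nlon)
  n_coastal <- round(config$coastal_fraction * npix)
  if (n_coastal > 0) bathy[sample.int(npix, n_coastal)] <- 50
  dims <- c(nlat, nlon, config$n_years)
  tr <- list(initiation = array(NA_real_, dims),
             termination = array(NA_real_, dims))
  for (y in seq_len(config$n_years)) {
    tr$initiation[, , y] <- ifelse(se_block, truth_se$initiation[y],
                                   truth_main$initiation[y])
    tr$termination[, , y] <- ifelse(se_block, truth_se$termination[y],
                                    truth_main$termination[y])
  }
  tr$duration <- tr$termination - tr$initiation
  list(chl = gridded_field(vals, lat = lat, lon = lon, units = "mg m-3",
                           variable = "chlor_a"),
       bathymetry = bathy, truth = tr, se_block = se_block,
       warm = truth_main$warm)
}

#' Generate synthetic temperature profiles with planted mixed-layer depth
#'
#' Each time step is a two-layer column: a uniform mixed layer down to the
#' planted depth `D(t)` (sinusoidal between the summer minimum and winter
#' maximum, deepest at the bloom centre, substantially shallower in warm
#' winters), then a linear thermocline cooling at `thermocline_gradient`.
#' Model-like output: no observation noise, so `D(t)` is recoverable to
#' within the interpolation tolerance of the depth grid.
#'
#' @param config a [synthetic_config()].
#' @return list: `profiles` ([temperature_profile_series()]) and `truth_mld`,
#'   the planted depth series (m).
#' @export
generate_temperature_profiles <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- planted_truth(config)
  D <- mld_signal(config, truth)
  depths <- seq(0, config$depth_max, by = config$depth_step)
  if (max(D) > config$depth_max)
    stop("planted mixed-layer depth exceeds the deepest profile level")
  surf <- sst_signal(config, truth)
  temp <- outer(seq_along(D), seq_along(depths), function(t, z)
    surf[t] - config$thermocline_gradient * pmax(0, depths[z] - D[t]))
  list(profiles = temperature_profile_series(temp, depth_levels = depths),
       truth_mld = D)
}
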