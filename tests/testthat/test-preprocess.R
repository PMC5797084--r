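test_that("8-day compositing averages available days per bin", {
  expect_equal(composite_to_8day(rep(25, 8))$values, 25)
  expect_equal(composite_to_8day(1:8)$values, 4.5)
  # a 365-day year gives 46 bins, the last averaging the residual days
  set.seed(1)
  daily <- rnorm(365)
  got <- composite_to_8day(daily)
  expect_length(got$values, 46)
  want <- sapply(1:46, function(b) {           # direct loop oracle
    mean(daily[((b - 1) * 8 + 1):min(b * 8, 365)])
  })
  expect_equal(got$values, want)
  # empty bins propagate as NA
  daily[9:16] <- NA
  expect_true(is.na(composite_to_8day(daily)$values[2]))
})

test_that("spatial averaging is the per-time mean over valid pixels", {
  vals <- array(3, dim = c(5, 4, 4))
  fld <- gridded_field(vals, lat = 1:4, lon = 1:4)
  expect_equal(spatial_average(fld)$values, rep(3, 5))
  vals[2, 1, 1] <- NA
  vals[3, 2, 3] <- 9
  fld <- gridded_field(vals, lat = 1:4, lon = 1:4)
  got <- spatial_average(fld)$values
  expect_equal(got[2], 3)                      # masked pixel ignored
  expect_equal(got[3], mean(c(rep(3, 15), 9)))
  # brute-force oracle on a synthetic scene
  scene <- generate_gridded_scene(synthetic_config(n_years = 2,
                                                   grid_shape = c(5, 5)))
  got <- spatial_average(scene$chl)$values
  want <- sapply(seq_len(dim(scene$chl$values)[1]), function(t) {
    x <- as.vector(scene$chl$values[t, , ])
    mean(x[!is.na(x)])
  })
  expect_equal(got, want)
  # excluding every pixel is an error
  expect_error(spatial_average(fld, matrix(TRUE, 4, 4)), "excluded")
})

test_that("outlier flagging is robust and spares clean series", {
  expect_warning(f <- flag_outliers(rep(0.2, 20)), "zero MAD")
  expect_false(any(f))
  v <- rnorm(50, 0.2, 0.01)
  v[17] <- 20
  f <- flag_outliers(v, k = 5)
  expect_true(f[17])
  expect_equal(sum(f), 1)
  # three spikes planted in a synthetic record, flagged against the robust
  # seasonal cycle: all three caught, no false positives
  set.seed(3)
  reg <- generate_regional_series(synthetic_config(missing_fraction = 0,
                                                   warm_years = integer(0)))
  v <- reg$chl$values
  spikes <- c(40L, 300L, 700L)
  v[spikes] <- v[spikes] + 5
  f <- flag_outliers(v, k = 5, periods_per_year = 46)
  expect_identical(which(f), spikes)
  expect_error(flag_outliers(rep(1, 5)), "at least 12")
})

test_that("least-squares in-painting fills gaps smoothly", {
  expect_equal(fill_gaps(c(0.2, NA, 0.4))[2], 0.3)
  v <- sin(1:40 / 5)
  expect_identical(fill_gaps(v), v)            # identity when complete
  # sinusoid with 20% random gaps: RMSE under 10% of amplitude
  set.seed(11)
  truth <- sin(2 * pi * (1:184) / 46)
  gappy <- truth
  gappy[sample(184, 37)] <- NA
  filled <- fill_gaps(gappy)
  expect_lt(sqrt(mean((filled - truth)^2)), 0.1)
  expect_error(fill_gaps(rep(NA_real_, 10)), "entirely missing")
  expect_error(fill_gaps(c(1, 2, rep(NA, 8))), "50%")
})

test_that("climatology fill substitutes the per-period multi-year mean", {
  v <- rep(c(1, 2, 3, 4), 5)                   # 4-period years
  v[c(2, 7)] <- NA
  filled <- fill_gaps(v, method = "climatology", periods_per_year = 4)
  expect_equal(filled[2], 2)
  expect_equal(filled[7], 3)
  expect_identical(fill_gaps(rep(c(1, 2), 10), "climatology", 2),
                   rep(c(1, 2), 10))
})

test_that("anomalies subtract the declared baseline", {
  expect_equal(as.numeric(compute_anomalies(rep(2.5, 30))), rep(0, 30))
  seasonal <- rep(sin(2 * pi * (1:46) / 46), 4)
  clim_an <- compute_anomalies(seasonal, "climatological")
  expect_equal(as.numeric(clim_an), rep(0, 184))
  set.seed(5)
  v <- rnorm(92, 10)
  expect_equal(as.numeric(compute_anomalies(v)), v - mean(v))
  expect_lt(abs(sum(compute_anomalies(v))), 1e-9 * length(v))
})

test_that("standardisation yields unit variance and rejects zero variance", {
  a <- compute_anomalies(c(1, 3, 5, 3, 1, 3, 5, 3))
  z <- standardise(a)
  expect_equal(stats::sd(z), 1)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_true(attr(z, "standardised"))
  expect_error(standardise(compute_anomalies(rep(2, 10))), "variance")
})

test_that("window averages follow the bloom-year convention", {
  expect_equal(window_average(rep(7, 92), "winter"), c(7, 7))
  ramp <- rep(1:46, 2)
  expect_equal(window_average(ramp, 15:21), c(18, 18))
  # the full-year window reproduces the annual mean
  set.seed(8)
  v <- rnorm(3 * 46)
  expect_equal(window_average(v, 1:46),
               sapply(1:3, function(y) mean(v[((y - 1) * 46 + 1):(y * 46)])))
  expect_error(window_average(v, "august"), "unknown window")
  expect_error(window_average(v, 0:5), "1:periods_per_year")
})

test_that("compositing then averaging commutes with averaging then compositing", {
  set.seed(13)
  vals <- array(rnorm(80 * 3 * 3, 10), dim = c(80, 3, 3))
  fld <- gridded_field(vals, lat = 1:3, lon = 1:3)
  left <- composite_to_8day(regional_series(spatial_average(fld)$values,
                                            "daily"))$values
  per_pixel <- apply(vals, c(2, 3), function(ts)
    composite_to_8day(regional_series(ts, "daily"))$values)
  right <- apply(per_pixel, 1, mean)
  expect_equal(left, right, tolerance = 1e-10)
})

test_that("monthly aggregation yields 12 bins per year", {
  m <- composite_to_monthly(rep(1:46, 2))
  expect_length(m$values, 24)
  edges <- round(46 * (0:12) / 12)
  want <- sapply(1:12, function(i) mean((edges[i] + 1):edges[i + 1]))
  expect_equal(m$values[1:12], want)
})
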