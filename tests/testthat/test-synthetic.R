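test_that("configs are validated against their invariants", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(warm_amplitude_factor = 1.5), "0, 1")
  expect_error(synthetic_config(missing_fraction = 1), "missing_fraction")
  expect_error(synthetic_config(bloom_width = 0), "bloom_width")
  expect_error(synthetic_config(mld_winter_max = 10, mld_summer_min = 20),
               "mld_winter_max")
  # a warm-year bloom squeezed below one period is rejected
  expect_error(synthetic_config(bloom_width = 3, warm_initiation_delay = 3,
                                warm_termination_advance = 3),
               "shorter than 1 period")
})

test_that("noiseless construction plants the configured timings", {
  cfg <- noiseless_config(warm_years = integer(0), bloom_center_period = 19,
                          bloom_width = 7)
  reg <- generate_regional_series(cfg)
  expect_true(all(reg$truth$initiation == 12))
  expect_true(all(reg$truth$termination == 26))
  # warm-year truth shifts by exactly the configured delay
  cfg2 <- noiseless_config(warm_initiation_delay = 3)
  tr <- generate_regional_series(cfg2)$truth
  expect_true(all(tr$initiation[tr$warm] == tr$initiation[!tr$warm][1] + 3))
})

test_that("generated fields are bit-reproducible under a fixed seed", {
  cfg <- synthetic_config(n_years = 3, grid_shape = c(5, 5), seed = 99)
  expect_identical(generate_regional_series(cfg),
                   generate_regional_series(cfg))
  expect_identical(generate_gridded_scene(cfg), generate_gridded_scene(cfg))
  expect_identical(generate_temperature_profiles(cfg),
                   generate_temperature_profiles(cfg))
  # a different seed moves the noise
  cfg2 <- synthetic_config(n_years = 3, grid_shape = c(5, 5), seed = 100)
  expect_false(identical(generate_regional_series(cfg)$chl$values,
                         generate_regional_series(cfg2)$chl$values))
})

test_that("regional climatologies carry the planted chl-SST anti-phase", {
  reg <- generate_regional_series(synthetic_config())
  rho <- stats::cor(climatology(fill_gaps(reg$chl$values)),
                    climatology(reg$sst$values), method = "spearman")
  expect_lt(rho, -0.9)
  # planted warm years are warm, cold years cold, over the bloom peak
  anoms <- aggregate_driver(reg$sst$values, "bloom_peak")
  warm <- reg$truth$warm
  expect_true(all(anoms[warm] > 0))
  expect_true(all(anoms[!warm] < 0))
})

test_that("gridded scenes plant spatial structure and missingness", {
  cfg <- noiseless_config(n_years = 2, grid_shape = c(8, 8),
                          southeast_delay = 0, coastal_fraction = 0.25)
  scene <- generate_gridded_scene(cfg)
  # no spatial offset -> identical truth at every pixel
  expect_equal(length(unique(as.vector(scene$truth$initiation[, , 1]))), 1)
  expect_equal(sum(scene$bathymetry < 100), 16)
  # southeast block is planted exactly southeast_delay periods later
  cfg2 <- noiseless_config(n_years = 2, southeast_delay = 2)
  sc2 <- generate_gridded_scene(cfg2)
  ini <- sc2$truth$initiation[, , 1]
  expect_true(all(ini[sc2$se_block] - ini[!sc2$se_block][1] == 2))
  # missingness is the configured fraction, at random
  cfg3 <- synthetic_config(n_years = 2, grid_shape = c(6, 6),
                           missing_fraction = 0.2)
  sc3 <- generate_gridded_scene(cfg3)
  n_total <- length(sc3$chl$values)
  expect_equal(sum(is.na(sc3$chl$values)), round(0.2 * n_total))
  expect_error(generate_gridded_scene(synthetic_config(grid_shape = c(3, 8))),
               "grid too small")
})

test_that("temperature profiles carry the planted mixed layer", {
  # near-constant planted depth with a sharp interface
  cfg <- synthetic_config(mld_winter_max = 100, mld_summer_min = 99.99,
                          n_years = 2)
  gen <- generate_temperature_profiles(cfg)
  expect_true(all(abs(gen$truth_mld - 100) < 0.02))
  mld <- compute_mld(gen$profiles)
  expect_true(all(abs(mld$values - 100) <= cfg$depth_step))
  # cold-year winter maxima exceed warm-year winter maxima by construction
  cfg2 <- synthetic_config(n_years = 4, warm_years = c(2, 4))
  tr <- matrix(generate_temperature_profiles(cfg2)$truth_mld, nrow = 46)
  expect_gt(min(apply(tr[, c(1, 3)], 2, max)), max(apply(tr[, c(2, 4)], 2, max)))
  expect_error(generate_temperature_profiles(
    synthetic_config(mld_winter_max = 500, depth_max = 300)),
    "deepest profile level")
})
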