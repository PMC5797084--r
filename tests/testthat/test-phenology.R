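test_that("threshold is the whole-record median elevated by the fraction", {
  s <- c(rep(0.2, 30), rep(0.5, 10), rep(0.2, 6))
  expect_equal(compute_threshold(s, 0.15), 0.2 * 1.15)
  expect_equal(compute_threshold(s, 0), stats::median(s))
  expect_error(compute_threshold(numeric(0)), "empty")
  # independent check on a generated record
  reg <- generate_regional_series(noiseless_config())
  expect_equal(compute_threshold(reg$chl),
               stats::median(reg$chl$values) * 1.15)
})

test_that("bloom years tile the series and partial years are dropped", {
  expect_equal(nrow(split_bloom_years(rep(0, 3 * 46))), 3)
  expect_warning(w <- split_bloom_years(rep(0, 3 * 46 + 10)), "trailing")
  expect_equal(nrow(w), 3)
  expect_equal(w$start, c(1, 47, 93))
  expect_equal(w$end, c(46, 92, 138))
  expect_error(split_bloom_years(rep(0, 20)), "shorter")
  expect_equal(nrow(split_bloom_years(rep(0, 18 * 46))), 18)
})

test_that("detect_bloom reads timing off the threshold-crossing episode", {
  expect_true(detect_bloom(rep(0.2, 46), 0.23)$no_bloom)
  v <- rep(0.2, 46); v[10:20] <- 0.5
  res <- detect_bloom(v, 0.23)
  expect_equal(res$initiation, 10)
  expect_equal(res$termination, 21)
  expect_equal(res$duration, 11)
  expect_false(res$no_bloom)
  # two disjoint episodes: indices must describe the one holding the maximum
  v2 <- rep(0.2, 46); v2[5:8] <- 0.4; v2[30:40] <- 0.6
  res2 <- detect_bloom(v2, 0.23)
  expect_equal(res2$initiation, 30)
  expect_equal(res2$peak, 30)          # earliest of the tied maxima
  expect_equal(res2$termination, 41)
  # an isolated single-period excursion is not a bloom
  v3 <- rep(0.2, 46); v3[12] <- 0.9
  expect_true(detect_bloom(v3, 0.23, min_duration = 2)$no_bloom)
  expect_false(detect_bloom(v3, 0.23, min_duration = 1)$no_bloom)
  expect_error(detect_bloom(c(NA, rep(0.2, 45)), 0.23), "NA")
})

test_that("detect_bloom agrees with the brute-force episode oracle", {
  set.seed(42)
  for (i in 1:300) {
    v <- random_year_series()
    th <- quantile(v, runif(1, 0.3, 0.9)) + rnorm(1, 0, 0.02)
    got <- detect_bloom(v, th)
    want <- oracle_detect_bloom(v, th)
    expect_identical(got$no_bloom, want$no_bloom)
    if (!got$no_bloom) {
      expect_identical(got$initiation, want$initiation)
      expect_identical(got$peak, want$peak)
      expect_identical(got$termination, want$termination)
      expect_identical(got$duration, want$duration)
    }
  }
})

test_that("raising the threshold never widens the detected episode", {
  set.seed(7)
  for (i in 1:50) {
    v <- rep(0.2, 46)
    w <- sample(3:20, 1); s <- sample(46 - w, 1)
    v[s:(s + w - 1)] <- v[s:(s + w - 1)] +
      0.5 * bloomphen:::bump_shape(w, 0.2) + rnorm(w, 0, 0.01)
    prev <- NULL
    for (th in seq(0.22, 0.5, by = 0.04)) {
      cur <- detect_bloom(v, th, min_duration = 1)
      if (!is.null(prev) && !prev$no_bloom && !cur$no_bloom) {
        expect_gte(cur$initiation, prev$initiation)
        expect_lte(cur$termination, prev$termination)
      }
      prev <- cur
    }
  }
})

test_that("phenology anomalies are centred on bloom years only", {
  idx <- data.frame(year = 1:2, initiation = c(10, 14), peak = c(15, 17),
                    termination = c(26, 24), duration = c(16, 10),
                    peak_chl = 0.5, no_bloom = FALSE)
  an <- phenology_anomalies(idx)
  expect_equal(an$initiation, c(-2, 2))
  expect_equal(an$termination, c(1, -1))
  # identical timing -> all-zero anomalies
  idx2 <- idx; idx2$initiation <- 12; idx2$termination <- 25; idx2$duration <- 13
  expect_true(all(phenology_anomalies(idx2)$initiation == 0))
  # no-bloom years drop out of baseline and output
  idx3 <- rbind(idx, data.frame(year = 3, initiation = NA, peak = NA,
                                termination = NA, duration = NA,
                                peak_chl = NA, no_bloom = TRUE))
  expect_equal(nrow(phenology_anomalies(idx3)), 2)
  expect_equal(phenology_anomalies(idx3)$initiation, c(-2, 2))
  expect_error(phenology_anomalies(idx3[c(1, 3), ]), "at least 2")
})

test_that("per-pixel phenology masks coastal pixels and honours planted offsets", {
  cfg <- noiseless_config(n_years = 4, grid_shape = c(6, 6),
                          coastal_fraction = 0.25, southeast_delay = 2)
  scene <- generate_gridded_scene(cfg)
  maps <- phenology_per_pixel(scene$chl, scene$bathymetry)
  expect_identical(maps$coastal_mask, scene$bathymetry < 100)
  expect_equal(sum(maps$coastal_mask), round(0.25 * 36))
  expect_true(all(is.na(maps$initiation[rep(maps$coastal_mask, 4)])))
  open <- !maps$coastal_mask
  for (y in 1:4) {
    ini <- maps$initiation[, , y]
    expect_equal(ini[open], scene$truth$initiation[, , y][open])
    ter <- maps$termination[, , y]
    expect_equal(ter[open], scene$truth$termination[, , y][open])
  }
  # southeast pixels bloom exactly southeast_delay periods later
  se <- scene$se_block & open
  nw <- !scene$se_block & open
  expect_true(all(maps$initiation[, , 1][se] ==
                    maps$initiation[, , 1][nw][1] + 2))
})

test_that("pixels with excessive missing data are dropped with a message", {
  cfg <- noiseless_config(n_years = 2, grid_shape = c(4, 4))
  scene <- generate_gridded_scene(cfg)
  scene$chl$values[1:80, 2, 2] <- NA   # 80/92 missing at one pixel
  expect_message(maps <- phenology_per_pixel(scene$chl, scene$bathymetry),
                 "dropped")
  expect_true(maps$excluded_mask[2, 2])
  expect_true(all(is.na(maps$initiation[2, 2, ])))
})
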