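# Independent brute-force oracles, written as direct scans so they share no
# code path with the implementation under test.

# Enumerate above-threshold episodes by walking the series point by point,
# pick the episode containing the (earliest) global maximum, and read the
# phenology straight off the episode edges.
oracle_detect_bloom <- function(v, threshold, min_duration = 2L) {
  n <- length(v)
  episodes <- list()
  start <- NA_integer_
  for (t in seq_len(n)) {
    if (v[t] > threshold && is.na(start)) start <- t
    if ((v[t] <= threshold || t == n) && !is.na(start)) {
      end <- if (v[t] > threshold) t else t - 1L
      episodes[[length(episodes) + 1L]] <- c(start, end)
      start <- NA_integer_
    }
  }
  none <- data.frame(initiation = NA_integer_, peak = NA_integer_,
                     termination = NA_integer_, duration = NA_integer_,
                     peak_chl = NA_real_, no_bloom = TRUE)
  if (length(episodes) == 0L) return(none)
  peak <- 1L
  for (t in seq_len(n)) if (v[t] > v[peak]) peak <- t   # earliest max
  sel <- NULL
  for (ep in episodes) if (ep[1] <= peak && peak <= ep[2]) sel <- ep
  init <- sel[1]
  term <- sel[2] + 1L
  if (term - init < min_duration) return(none)
  data.frame(initiation = init, peak = peak, termination = term,
             duration = term - init, peak_chl = v[peak], no_bloom = FALSE)
}

# random 46-point series spanning the regimes the detector must handle:
# flat records near the threshold, one or two planted bumps, smooth cycles
random_year_series <- function() {
  kind <- sample(4, 1)
  base <- runif(1, 0.1, 0.3)
  v <- rep(base, 46) + rnorm(46, 0, runif(1, 0.005, 0.08))
  if (kind >= 2) {
    w <- sample(2:18, 1)
    s <- sample(46 - w, 1)
    v[s:(s + w - 1)] <- v[s:(s + w - 1)] + runif(1, 0.05, 0.5)
  }
  if (kind == 3) {
    w2 <- sample(1:10, 1)
    s2 <- sample(46 - w2, 1)
    v[s2:(s2 + w2 - 1)] <- v[s2:(s2 + w2 - 1)] + runif(1, 0.05, 0.5)
  }
  if (kind == 4) v <- v + 0.2 * sin(2 * pi * (1:46) / 46 + runif(1, 0, 2 * pi))
  v
}

# the default synthetic study, generated once and reused across test files
pipeline_cache <- new.env(parent = emptyenv())
default_pipeline <- function() {
  if (is.null(pipeline_cache$res))
    pipeline_cache$res <- suppressMessages(run_pipeline(synthetic_config()))
  pipeline_cache$res
}

noiseless_config <- function(...) {
  synthetic_config(noise_sd_chl = 0, noise_sd_sst = 0, noise_sd_heatflux = 0,
                   missing_fraction = 0, ...)
}
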