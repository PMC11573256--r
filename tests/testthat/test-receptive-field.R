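# Build an fra object directly from a deterministic count matrix.
make_fra <- function(counts, grid) {
  structure(
    list(
      counts = counts, frequencies = grid$frequencies,
      intensities = grid$intensities, window = c(0, 32)
    ),
    class = "fra"
  )
}

# Noiseless expected-count matrix for a tuned site (10 spikes at full drive).
noiseless_counts <- function(grid, cf, threshold, bw10 = 1.0, bw40 = 2.0,
                             peak_count = 10) {
  site <- site_params(
    cf = cf, threshold = threshold, bw10 = bw10, bw40 = bw40,
    onset_latency = 8, peak_latency = 13, end_of_peak = 27,
    spontaneous_rate = 0, depth = 2000, peak_driven_rate = 1
  )
  st <- grid$stimuli
  w <- icresponse:::tuning_weight(st$frequency, st$intensity, site)
  matrix(peak_count * w, nrow = length(grid$frequencies))
}

test_that("FRA assembly maps responses onto the (frequency, intensity) matrix", {
  grid <- build_tone_grid(1000, 4000, 0.5, 0, 20, 10) # 5 x 3
  ids <- grid$stimuli$stimulus_id
  silent <- setNames(replicate(15, list(numeric(0)), simplify = FALSE), ids)
  fra0 <- build_fra(silent, grid)
  expect_equal(dim(fra0$counts), c(5, 3))
  expect_true(all(fra0$counts == 0))

  ones <- setNames(replicate(15, list(5), simplify = FALSE), ids)
  expect_true(all(build_fra(ones, grid)$counts == 1))

  expect_error(build_fra(ones[-1], grid), "missing tone responses")
})

test_that("FRA nonzero cells lie inside the generator tuning surface (near-noiseless)", {
  grid <- build_tone_grid(1000, 32000, 0.125, 0, 75, 5)
  cfg <- default_group_effects(n_sites = c(1, 1, 1, 1))
  coh <- generate_cohort(cfg, grid = grid, seed = 21, groups = "saline")
  site <- coh$sites[[1]]
  site$spontaneous_rate <- 0
  # re-simulate the same site with zero spontaneous rate
  set.seed(1)
  responses <- icresponse:::simulate_tone_grid_responses(
    site, grid, cfg$saline
  )
  fra <- build_fra(responses, grid)
  st <- grid$stimuli
  mask <- icresponse:::tuning_weight(st$frequency, st$intensity, site) > 0
  mask <- matrix(mask, nrow = length(grid$frequencies))
  expect_true(all(fra$counts[!mask] == 0))
  expect_gt(sum(fra$counts[mask]), 0)
})

test_that("receptive-field extraction recovers noiseless ground truth up to grid quantization", {
  grid <- build_tone_grid(1000, 32000, 0.0625, 0, 75, 5)
  fra <- make_fra(noiseless_counts(grid, cf = 10600, threshold = 35), grid)
  rf <- extract_rf(fra, spontaneous = 0)
  expect_true(rf$responsive)
  expect_equal(rf$threshold, 35)
  expect_lt(abs(log2(rf$cf / 10600)), 0.0625)
  expect_lt(abs(rf$bw10 - 1.0), 2 * 0.0625)
  expect_lt(abs(rf$bw40 - 2.0), 2 * 0.0625)
})

test_that("RF recovery is exact up to quantization across a (cf, threshold) sweep", {
  grid <- build_tone_grid(1000, 32000, 0.0625, 0, 75, 5)
  for (cf in c(2000, 4000, 8000, 12000, 22000)) {
    for (thr in c(5, 15, 20, 30, 35)) {
      fra <- make_fra(noiseless_counts(grid, cf, thr), grid)
      rf <- extract_rf(fra, spontaneous = 0)
      expect_true(rf$responsive)
      expect_equal(rf$threshold, thr)
      expect_lt(abs(log2(rf$cf / cf)), 2 * 0.0625)
      expect_lt(abs(rf$bw10 - 1.0), 2 * 0.0625)
    }
  }
})

test_that("unresponsive and boundary cases are marked, not errors", {
  grid <- build_tone_grid(1000, 32000, 0.0625, 0, 75, 5)
  zero <- make_fra(matrix(0, 81, 16), grid)
  rf0 <- extract_rf(zero, spontaneous = 0)
  expect_false(rf0$responsive)
  expect_true(is.na(rf0$cf) && is.na(rf0$threshold))

  # responsive only at 70-75 dB: threshold + 40 exceeds the grid maximum
  high <- make_fra(noiseless_counts(grid, cf = 8000, threshold = 70), grid)
  rf70 <- extract_rf(high, spontaneous = 0)
  expect_equal(rf70$threshold, 70)
  expect_true(is.na(rf70$bw40)) # 70 + 40 dB exceeds the 75-dB grid maximum
  expect_true(is.na(rf70$bw10)) # 70 + 10 dB does too
})

test_that("raising the response criterion never lowers the recovered threshold", {
  grid <- build_tone_grid(1000, 32000, 0.125, 0, 75, 5)
  set.seed(31)
  noisy <- noiseless_counts(grid, cf = 6000, threshold = 20, peak_count = 8) +
    matrix(rpois(41 * 16, 0.5), 41, 16)
  fra <- make_fra(noisy, grid)
  thresholds <- vapply(c(0.1, 0.2, 0.35, 0.5, 0.7), function(frac) {
    rf <- extract_rf(fra, spontaneous = 0.5 * 1000 / 32, criterion_frac = frac)
    if (rf$responsive) rf$threshold else Inf
  }, numeric(1))
  expect_true(all(diff(thresholds) >= 0))
})

test_that("latency metrics find onset, peak and end of the first excursion", {
  # all mass in bins [8,9) and [9,10), zero spontaneous
  trials <- list(c(8.1, 8.5, 9.2, 9.9), c(8.3, 9.4))
  psth <- compute_psth(trials, bin = 1, window = c(0, 40))
  lat <- latency_metrics(psth, spontaneous = 0)
  expect_equal(lat[["onset"]], 8)
  expect_equal(lat[["peak"]], 8.5)
  expect_equal(lat[["end_of_peak"]], 10)

  flat <- compute_psth(make_poisson_trials(20, 40, 5), bin = 1, window = c(0, 40))
  expect_true(all(is.na(latency_metrics(flat, spontaneous = 20))))
})

test_that("latency metrics recover generator latencies within one bin at high rate", {
  site <- site_params(
    cf = 8000, threshold = 20, bw10 = 1, bw40 = 2,
    onset_latency = 8.2, peak_latency = 13.4, end_of_peak = 27.1,
    spontaneous_rate = 5, depth = 2000, peak_driven_rate = 2000
  )
  eff <- group_effect_config("saline", 1)
  fn <- rate_profile(list(frequency = 8000, intensity = 60), site, eff)
  trials <- simulate_trials(fn, 50, 200, rng_seed = 17)
  psth <- compute_psth(trials, bin = 1, window = c(0, 40))
  lat <- latency_metrics(psth, spontaneous = 5)
  expect_lt(abs(lat[["onset"]] - 8.2), 1)
  expect_lt(abs(lat[["peak"]] - 13.4), 1.5) # transient is flat near its peak
  expect_lt(abs(lat[["end_of_peak"]] - 27.1), 1.5)
  expect_true(lat[["onset"]] <= lat[["peak"]])
  expect_true(lat[["peak"]] <= lat[["end_of_peak"]])
})

test_that("tonotopy summary: monotone maps, uniform occupancy, normalization", {
  depth <- seq(1000, 5000, length.out = 50)
  cf <- 1000 * 2^((depth - 1000) / 1000)
  cf <- pmin(cf, 32000)
  ts <- tonotopy_summary(cf, depth)
  expect_equal(ts$correlation, 1.0)
  expect_equal(sum(ts$percent_per_octave), 100)

  set.seed(41)
  cf_u <- 2^runif(4000, log2(1000), log2(32000))
  ts_u <- tonotopy_summary(cf_u, runif(4000, 1000, 5000))
  expect_true(all(abs(ts_u$percent_per_octave - 20) < 3 * sqrt(20 * 80 / 4000)))

  expect_error(tonotopy_summary(c(1000, 2000), c(1, 2)), "too few")
})
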