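test_that("vector strength closed forms", {
  period <- 100
  expect_equal(vector_strength(c(10, 110, 210, 310), period), 1.0)
  expect_equal(vector_strength(c(0, 50), period), 0.0) # antiphase pair
  expect_equal(vector_strength(c(0, 25), period), sqrt(2) / 2) # phases 0, pi/2
  expect_true(is.na(vector_strength(numeric(0), period)))
  expect_error(vector_strength(c(1, 2), 0), "period")
})

test_that("vector strength is invariant to shifts by whole periods", {
  set.seed(1)
  for (k in 1:10) {
    spikes <- runif(50, 0, 600)
    shifted <- spikes + sample(-3:3, 50, replace = TRUE) * 100
    expect_equal(
      vector_strength(spikes, 100), vector_strength(shifted, 100),
      tolerance = 1e-9
    )
  }
})

test_that("Rayleigh statistic is 2 n VS^2 with a significance flag", {
  expect_equal(as.numeric(rayleigh_statistic(1, 10)), 20)
  expect_true(attr(rayleigh_statistic(1, 10), "significant"))
  expect_equal(as.numeric(rayleigh_statistic(0, 500)), 0)
  expect_equal(as.numeric(rayleigh_statistic(0.5, 100)), 50)
  expect_false(attr(rayleigh_statistic(0.2, 100), "significant")) # 8 < 13.8
  # monotone in vs and in n
  vs_seq <- seq(0.1, 1, 0.1)
  expect_true(all(diff(vapply(vs_seq, function(v) {
    as.numeric(rayleigh_statistic(v, 50))
  }, numeric(1))) > 0))
  n_seq <- c(10, 50, 200, 1000)
  expect_true(all(diff(vapply(n_seq, function(n) {
    as.numeric(rayleigh_statistic(0.3, n))
  }, numeric(1))) > 0))
})

test_that("uniform phases give E[2nVS^2] near 2 and rarely exceed 13.8", {
  set.seed(2)
  stats <- replicate(2000, {
    vs <- vector_strength(runif(500, 0, 600), 100)
    2 * 500 * vs^2
  })
  expect_lt(abs(mean(stats) - 2), 0.4) # exponential(2): SE = 2/sqrt(2000)
  expect_lt(mean(stats > 13.8), 0.005) # nominal e^(-6.9) ~ 1e-3
})

test_that("burst driven spikes average counts per burst with spontaneous correction", {
  train <- build_noise_train(10, 6, 25)
  trials <- replicate(
    10,
    as.vector(outer(c(5, 10, 15), train$onsets, "+")),
    simplify = FALSE
  )
  expect_equal(burst_driven_spikes(trials, train), 3.0)
  silent <- replicate(10, numeric(0), simplify = FALSE)
  expect_equal(burst_driven_spikes(silent, train), 0.0)
  expect_error(
    burst_driven_spikes(trials, train, response_window = 150),
    "inter-burst"
  )

  set.seed(3)
  sim <- replicate(500, {
    sort(unlist(lapply(train$onsets, function(o) o + runif(rpois(1, 4), 0, 100))))
  }, simplify = FALSE)
  se <- sqrt(4 / (6 * 500))
  expect_lt(abs(burst_driven_spikes(sim, train) - 4), 3 * se)
})

test_that("burst latencies: median first spike and first-excursion peak bin", {
  train <- build_noise_train(10, 6, 25)
  trials <- replicate(9, c(7.0, 40, 80), simplify = FALSE)
  expect_equal(burst_latencies(trials, train)[["onset"]], 7.0)

  dense <- replicate(30, c(11.7, 12.1, 12.5, 12.9), simplify = FALSE)
  expect_equal(burst_latencies(dense, train)[["peak"]], 12.5)

  empty <- replicate(5, numeric(0), simplify = FALSE)
  expect_true(is.na(burst_latencies(empty, train)[["onset"]]))
})

test_that("temporal metrics on synthetic phase-locked trains are internally consistent", {
  train <- build_noise_train(10, 6, 25)
  cfg <- default_group_effects(n_sites = c(1, 1, 1, 1))
  coh <- generate_cohort(cfg, train = train, seed = 13, groups = "saline")
  s <- coh$sites[[1]]
  tm <- temporal_metrics(s$responses$burst_train, train, s$spontaneous_rate)
  expect_true(tm$vector_strength > 0 && tm$vector_strength <= 1)
  expect_equal(tm$rayleigh, 2 * tm$n_spikes * tm$vector_strength^2)
  expect_true(tm$rayleigh_significant)
  expect_gt(tm$driven_spikes_per_burst, 0)
})

test_that("a configured burst onset advance is recovered from median first-spike latencies", {
  train <- build_noise_train(10, 6, 25)
  cfg <- default_group_effects(n_sites = c(150, 1, 1, 150))
  coh <- generate_cohort(cfg,
    train = train, seed = 19,
    groups = c("saline", "vpa_vns_tone")
  )
  m <- site_metrics(coh, stages = "bursts")
  onset_means <- tapply(m$burst_onset_latency, m$group, mean, na.rm = TRUE)
  diff_onset <- onset_means[["saline"]] - onset_means[["vpa_vns_tone"]]
  expect_lt(abs(diff_onset - 1.0), 0.5)
})
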