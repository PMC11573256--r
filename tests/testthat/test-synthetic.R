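make_test_site <- function(spont = 10, pdr = 500) {
  site_params(
    cf = 8000, threshold = 20, bw10 = 1.0, bw40 = 2.0,
    onset_latency = 8.2, peak_latency = 13.4, end_of_peak = 27.1,
    spontaneous_rate = spont, depth = 2500, peak_driven_rate = pdr
  )
}

neutral_effects <- function(...) {
  group_effect_config("saline", n_sites = 1, ...)
}

test_that("tone rate profile is spontaneous-only outside the tuning extent", {
  site <- make_test_site()
  eff <- neutral_effects()
  far_tone <- list(frequency = 1000, intensity = 30) # 3 octaves from CF at thr+10
  fn <- rate_profile(far_tone, site, eff)
  tt <- seq(0, 50, 0.5)
  expect_equal(fn(tt), rep(site$spontaneous_rate, length(tt)))
})

test_that("tone at CF 40 dB above threshold reaches the site's peak driven rate", {
  site <- make_test_site()
  eff <- neutral_effects(tone_gain = 1)
  fn <- rate_profile(list(frequency = 8000, intensity = 60), site, eff)
  tt <- seq(0, 50, 0.01)
  expect_equal(
    max(fn(tt)) - site$spontaneous_rate, site$peak_driven_rate,
    tolerance = 1e-6
  )
  # peak occurs at the configured peak latency
  expect_equal(tt[which.max(fn(tt))], site$peak_latency, tolerance = 0.02)
})

test_that("zero gains degenerate every profile to the spontaneous rate", {
  site <- make_test_site()
  eff <- neutral_effects(
    speech_gain = 0, consonant_gain = 0, vowel_gain = 0,
    tone_gain = 0, burst_gain = 0
  )
  tt <- seq(0, 400, 1)
  tone_fn <- rate_profile(list(frequency = 8000, intensity = 60), site, eff)
  tok <- speech_catalog()[2, ]
  speech_fn <- rate_profile(tok, site, eff)
  burst_fn <- rate_profile(build_noise_train(), site, eff)
  for (fn in list(tone_fn, speech_fn, burst_fn)) {
    expect_equal(fn(tt), rep(site$spontaneous_rate, length(tt)))
  }
})

test_that("unrecognized stimulus types are rejected", {
  expect_error(
    rate_profile("dad", make_test_site(), neutral_effects()),
    "unrecognized stimulus"
  )
})

test_that("simulated constant-rate trials have the Poisson mean count", {
  fn <- function(t) rep(50, length(t))
  attr(fn, "max_rate") <- 50
  trials <- simulate_trials(fn, 400, 1000, rng_seed = 42)
  counts <- lengths(trials)
  se <- sqrt(20 / 1000)
  expect_lt(abs(mean(counts) - 20), 3 * se)
  expect_true(all(vapply(trials, function(x) !is.unsorted(x), logical(1))))
  expect_true(all(unlist(trials) > 0 & unlist(trials) <= 400))
})

test_that("zero rate yields empty trials and same seed reproduces spike times", {
  zero <- function(t) rep(0, length(t))
  expect_true(all(lengths(simulate_trials(zero, 400, 20, rng_seed = 1)) == 0))

  fn <- function(t) 100 * exp(-t / 50)
  a <- simulate_trials(fn, 200, 10, rng_seed = 7)
  b <- simulate_trials(fn, 200, 10, rng_seed = 7)
  expect_identical(a, b)

  neg <- function(t) rep(-1, length(t))
  expect_error(simulate_trials(neg, 100, 5, rng_seed = 1), "negative rate")
})

test_that("cohort generation is deterministic and respects group structure", {
  cfg <- default_group_effects(n_sites = c(3, 2, 2, 2))
  speech <- speech_catalog(n_repeats = 5)
  c1 <- generate_cohort(cfg, speech = speech, seed = 11)
  c2 <- generate_cohort(cfg, speech = speech, seed = 11)
  expect_identical(
    lapply(c1$sites, `[[`, "responses"),
    lapply(c2$sites, `[[`, "responses")
  )
  expect_length(c1$sites, 9)
  groups <- vapply(c1$sites, `[[`, character(1), "group")
  expect_equal(unname(table(factor(groups, levels = ic_groups()))[1]), 3L)

  c3 <- generate_cohort(cfg, speech = speech, seed = 12)
  expect_false(identical(
    c1$sites[[1]]$responses$spont,
    c3$sites[[1]]$responses$spont
  ))

  expect_error(
    generate_cohort(cfg[c("saline", "vpa")], speech = speech, seed = 1),
    "missing group"
  )
})

test_that("default config encodes the calibrated group contrasts", {
  cfg <- default_group_effects()
  expect_equal(
    vapply(cfg, `[[`, numeric(1), "n_sites"),
    c(saline = 453, vpa = 374, vpa_vns_speech = 183, vpa_vns_tone = 146)
  )
  expect_equal(cfg$vpa_vns_tone$speech_gain / cfg$vpa$speech_gain, 1.44)
  expect_equal(cfg$vpa_vns_speech$speech_gain / cfg$vpa$speech_gain, 0.95)
  expect_lt(cfg$vpa$speech_gain, cfg$saline$speech_gain)
  expect_true(all(vapply(cfg, `[[`, numeric(1), "tone_gain") == 1))
})

test_that("configured speech gain ratios are recovered by the driven-rate pipeline", {
  cfg <- default_group_effects(n_sites = c(100, 100, 1, 1))
  coh <- generate_cohort(cfg,
    speech = speech_catalog(), seed = 3,
    groups = c("saline", "vpa")
  )
  m <- site_metrics(coh, stages = "speech")
  by_group <- split(m$speech_driven_whole, m$group)
  means <- vapply(by_group, mean, numeric(1))
  ses <- vapply(by_group, function(x) sd(x) / sqrt(length(x)), numeric(1))
  ratio <- means[["vpa"]] / means[["saline"]]
  se_ratio <- ratio * sqrt(
    (ses[["vpa"]] / means[["vpa"]])^2 + (ses[["saline"]] / means[["saline"]])^2
  )
  expect_lt(abs(ratio - 0.7), 3 * se_ratio)
})

test_that("generated cohorts are tonotopic by construction", {
  cfg <- default_group_effects(n_sites = c(80, 1, 1, 1))
  coh <- generate_cohort(cfg, seed = 5, groups = "saline")
  sites <- cohort_sites(coh)
  ts <- tonotopy_summary(sites$cf, sites$depth_um)
  expect_gte(ts$correlation, 0.9)
})
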