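# Trials with Poisson counts at `mean_count` spikes uniformly placed in a
# window — the generic classifier input for distribution-level tests.
count_trials <- function(mean_count, n_trials, window = c(0, 40)) {
  lapply(seq_len(n_trials), function(i) {
    sort(runif(rpois(1, mean_count), window[1], window[2]))
  })
}

test_that("identical trial sets are at exact chance under paired templates", {
  set.seed(1)
  trials <- count_trials(8, 20)
  res <- nn_classify_pair(trials, trials, binning_scheme("consonant"),
    tie_mode = "expected"
  )
  expect_equal(res$accuracy, 50)
  expect_equal(res$n_ties, res$n_decisions)
  expect_equal(res$n_decisions, 40)
})

test_that("the own-template variant penalizes identical sets (competing template contains the held-out trial)", {
  set.seed(2)
  trials <- count_trials(8, 20)
  res <- nn_classify_pair(trials, trials, binning_scheme("consonant"),
    tie_mode = "expected", template = "own"
  )
  expect_equal(res$accuracy, 0)
})

test_that("disjoint responses are perfectly discriminated", {
  set.seed(3)
  loud <- lapply(1:20, function(i) sort(runif(10, 0, 40))) # exactly 10 spikes
  silent <- replicate(20, numeric(0), simplify = FALSE)
  res <- nn_classify_pair(loud, silent, binning_scheme("consonant"))
  expect_equal(res$accuracy, 100)
})

test_that("a hand-enumerated 3+3 single-bin case is scored exactly", {
  scheme <- binning_scheme("custom", window = c(0, 10), bin = 10)
  mk <- function(counts) lapply(counts, function(k) seq_len(k) * 10 / (k + 1))
  # counts A = {0, 1, 5}, B = {2, 6, 7}. Hand enumeration of the six paired
  # leave-one-out folds: held-out 5 (A) lands nearer B's template and
  # held-out 2 (B) lands nearer A's template; the other four are correct.
  res <- nn_classify_pair(mk(c(0, 1, 5)), mk(c(2, 6, 7)), scheme,
    tie_mode = "expected"
  )
  expect_equal(res$accuracy, 100 * 4 / 6)
  expect_equal(res$n_decisions, 6)
})

test_that("classifier equals the exhaustive fold-enumeration oracle", {
  set.seed(4)
  scheme_c <- binning_scheme("consonant")
  scheme_v <- binning_scheme("vowel")
  for (k in 1:40) {
    n_a <- sample(2:5, 1)
    n_b <- sample(2:5, 1)
    a <- count_trials(sample(1:10, 1), n_a, window = c(0, 340))
    b <- count_trials(sample(1:10, 1), n_b, window = c(0, 340))
    scheme <- if (k %% 2) scheme_c else scheme_v
    got <- suppressWarnings(
      nn_classify_pair(a, b, scheme, tie_mode = "expected")
    )$accuracy
    want <- oracle_nn_accuracy(a, b, scheme$window, scheme$bin)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("accuracy is symmetric under label swap", {
  set.seed(5)
  for (k in 1:10) {
    a <- count_trials(6, 8)
    b <- count_trials(10, 8)
    scheme <- binning_scheme("consonant")
    expect_equal(
      nn_classify_pair(a, b, scheme, tie_mode = "expected")$accuracy,
      nn_classify_pair(b, a, scheme, tie_mode = "expected")$accuracy
    )
  }
})

test_that("unequal trial counts proceed with a warning; tiny sets error", {
  set.seed(6)
  expect_warning(
    nn_classify_pair(count_trials(5, 4), count_trials(5, 6), binning_scheme("consonant")),
    "trial counts differ"
  )
  expect_error(
    nn_classify_pair(count_trials(5, 1), count_trials(5, 5), binning_scheme("consonant")),
    "at least 2 trials"
  )
})

# A fake site whose speech responses are drawn i.i.d. from one rate.
make_uniform_site <- function(tokens, mean_count = 10, n_repeats = 20) {
  responses <- lapply(tokens, function(tok) count_trials(mean_count, n_repeats, c(0, 400)))
  names(responses) <- paste0("speech_", tokens)
  list(responses = responses)
}

test_that("consonant discrimination covers 36 pairs and sits at chance for identical profiles", {
  cat <- speech_catalog()
  set.seed(7)
  accs <- vapply(1:4, function(i) {
    site <- make_uniform_site(consonant_tokens(cat))
    consonant_discrimination(site, cat, tie_mode = "expected")$mean_accuracy
  }, numeric(1))
  one <- consonant_discrimination(make_uniform_site(consonant_tokens(cat)), cat)
  expect_equal(nrow(one$results), 36)
  expect_lt(abs(mean(accs) - 50), 8)

  broken <- make_uniform_site(setdiff(consonant_tokens(cat), "shad"))
  expect_error(consonant_discrimination(broken, cat), "shad")
})

test_that("vowel discrimination separates tokens by vowel-window count", {
  cat <- speech_catalog()
  set.seed(8)
  # vowel-window mean counts 20 / 5 / 20 for dad / deed / dood
  responses <- list(
    speech_dad = count_trials(20, 20, c(40, 340)),
    speech_deed = count_trials(5, 20, c(40, 340)),
    speech_dood = count_trials(20, 20, c(40, 340))
  )
  site <- list(responses = responses)
  vd <- vowel_discrimination(site, cat, tie_mode = "expected")
  expect_equal(nrow(vd$results), 3)
  res <- vd$results
  acc <- function(a, b) res$accuracy[res$token_a == a & res$token_b == b]
  expect_gt(acc("dad", "deed"), 85)
  expect_gt(acc("deed", "dood"), 85)
  expect_lt(abs(acc("dad", "dood") - 50), 25)
})

test_that("accuracy is nondecreasing as response separation grows", {
  set.seed(9)
  scheme <- binning_scheme("vowel")
  base <- 10
  accs <- vapply(c(0, 6, 15), function(sep) {
    mean(vapply(1:10, function(i) {
      a <- count_trials(base, 20, c(40, 340))
      b <- count_trials(base + sep, 20, c(40, 340))
      nn_classify_pair(a, b, scheme, tie_mode = "expected")$accuracy
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_lt(abs(accs[1] - 50), 10)
  expect_gt(accs[3], 85)
})
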