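#' Per-group response-effect configuration
#'
#' Parameters driving the synthetic cohort generator for one experimental
#' group. Gains are multiplicative factors on driven response components;
#' latency shifts are additive, in ms.
#'
#' `speech_gain` is defined as the whole-window (0-400 ms) gain on the
#' driven speech response. `consonant_gain` and `vowel_gain` redistribute
#' driven spikes between the consonant (0-40 ms) and vowel (40-340 ms)
#' windows without changing the whole-window driven integral (an internal
#' normalization rescales both components), so group contrasts on the
#' whole-window driven rate equal the `speech_gain` ratio exactly in
#' expectation.
#'
#' @param group Group label, one of [ic_groups()].
#' @param n_sites Number of recording sites to simulate.
#' @param speech_gain Whole-window gain on driven speech responses.
#' @param consonant_gain,vowel_gain Window-shape modifiers (see above).
#' @param tone_gain Gain on driven tone responses.
#' @param burst_gain Gain on driven noise-burst responses.
#' @param burst_onset_shift,burst_peak_shift Additive shifts of the burst
#'   response onset and peak/end latencies, ms (negative = earlier).
#' @param mean_threshold Group-mean tone response threshold, dB SPL.
#' @param n_animals Number of animals the sites are attributed to.
#' @return An object of class `group_effects`.
#' @export
group_effect_config <- function(group, n_sites,
                                speech_gain = 1, consonant_gain = 1,
                                vowel_gain = 1, tone_gain = 1,
                                burst_gain = 1, burst_onset_shift = 0,
                                burst_peak_shift = 0,
                                mean_threshold = 17.35, n_animals = 1) {
  group <- match.arg(group, IC_GROUPS)
  gains <- c(speech_gain, consonant_gain, vowel_gain, tone_gain, burst_gain)
  if (any(gains < 0)) stop("gains must be non-negative")
  if (!(n_sites >= 1)) stop("n_sites must be at least 1")
  structure(
    list(
      group = group, n_sites = as.integer(n_sites),
      speech_gain = speech_gain, consonant_gain = consonant_gain,
      vowel_gain = vowel_gain, tone_gain = tone_gain,
      burst_gain = burst_gain, burst_onset_shift = burst_onset_shift,
      burst_peak_shift = burst_peak_shift,
      mean_threshold = mean_threshold, n_animals = as.integer(n_animals)
    ),
    class = "group_effects"
  )
}

#' Default four-group effect configuration
#'
#' The packaged calibration of the synthetic cohort. It encodes the group
#' contrasts the pipeline is designed to detect:
#' \itemize{
#'   \item VPA speech responses are degraded relative to saline
#'     (speech_gain 0.70 vs 1.00);
#'   \item VNS-tone pairing raises the VPA whole-window speech response by
#'     44\% (speech_gain 1.44 x 0.70) and strengthens/advances burst
#'     responses (burst_gain 1.30, onset and peak shifts -1 ms);
#'   \item VNS-speech pairing lowers the whole-window speech response by 5\%
#'     relative to VPA (speech_gain 0.95 x 0.70) while shifting driven
#'     spikes from the consonant to the vowel window (consonant_gain 0.85,
#'     vowel_gain 1.25) and weakening burst responses (burst_gain 0.85);
#'   \item tone responses are equal across groups (tone_gain 1 everywhere);
#'   \item group-mean tone thresholds are 17.35, 17.35, 17.78 and 12.35 dB
#'     SPL for saline, VPA, VPA+VNS-speech and VPA+VNS-tone.
#' }
#' Default site counts are 453 / 374 / 183 / 146 attributed to
#' 19 / 18 / 8 / 7 animals.
#'
#' @param n_sites Optional length-4 vector (named by group or in canonical
#'   order) overriding per-group site counts.
#' @return Named list of four [group_effect_config()] objects.
#' @export
default_group_effects <- function(n_sites = NULL) {
  n_default <- c(saline = 453L, vpa = 374L, vpa_vns_speech = 183L, vpa_vns_tone = 146L)
  if (!is.null(n_sites)) {
    if (length(n_sites) == 1) n_sites <- rep(n_sites, 4)
    if (is.null(names(n_sites))) names(n_sites) <- IC_GROUPS
    n_default[names(n_sites)] <- n_sites
  }
  vpa_speech <- 0.70
  list(
    saline = group_effect_config("saline", n_default[["saline"]],
      speech_gain = 1.00, mean_threshold = 17.35, n_animals = 19
    ),
    vpa = group_effect_config("vpa", n_default[["vpa"]],
      speech_gain = vpa_speech, mean_threshold = 17.35, n_animals = 18
    ),
    vpa_vns_speech = group_effect_config("vpa_vns_speech", n_default[["vpa_vns_speech"]],
      speech_gain = 0.95 * vpa_speech, consonant_gain = 0.85,
      vowel_gain = 1.25, burst_gain = 0.85,
      mean_threshold = 17.78, n_animals = 8
    ),
    vpa_vns_tone = group_effect_config("vpa_vns_tone", n_default[["vpa_vns_tone"]],
      speech_gain = 1.44 * vpa_speech, burst_gain = 1.30,
      burst_onset_shift = -1, burst_peak_shift = -1,
      mean_threshold = 12.35, n_animals = 7
    )
  )
}

# Raised-cosine transient: 0 at `onset`, 1 at `peak`, back to 0 at `end`,
# identically 0 outside [onset, end]. Smooth, with an exact return to
# baseline (which an alpha function lacks). Integral = (end - onset) / 2.
transient_kernel <- function(t, onset, peak, end) {
  k <- numeric(length(t))
  r <- t >= onset & t < peak
  if (any(r)) k[r] <- 0.5 * (1 - cos(pi * (t[r] - onset) / (peak - onset)))
  d <- t >= peak & t <= end
  if (any(d)) k[d] <- 0.5 * (1 + cos(pi * (t[d] - peak) / (end - peak)))
  k
}

# V-shaped tuning surface in [0, 1]. Zero below threshold; above it, the
# responsive frequency extent (octaves) widens linearly through bw10 at
# threshold+10 dB and bw40 at threshold+40 dB (clamped to [min_extent,
# bw40]); amplitude ramps from 0.6 at threshold to 1 at threshold+40 dB.
tuning_weight <- function(frequency, intensity, site, min_extent = 0.15) {
  thr <- site$threshold
  bw10 <- site$bw10
  bw40 <- site$bw40
  extent <- bw10 + (bw40 - bw10) * (intensity - thr - 10) / 30
  extent <- pmin(pmax(extent, min_extent), bw40)
  amp <- pmin(1, 0.6 + 0.4 * (intensity - thr) / 40)
  off <- intensity < thr | abs(log2(frequency / site$cf)) > extent / 2
  ifelse(off, 0, amp)
}

#' Site parameter bundle
#'
#' Ground-truth response parameters for one simulated multiunit site.
#'
#' @param cf Characteristic frequency, Hz.
#' @param threshold Tone response threshold, dB SPL.
#' @param bw10,bw40 Receptive-field widths 10/40 dB above threshold, octaves.
#' @param onset_latency,peak_latency,end_of_peak Transient latencies, ms.
#' @param spontaneous_rate Background rate, Hz.
#' @param depth Recording depth, micrometers.
#' @param peak_driven_rate Peak instantaneous driven rate at full drive, Hz.
#' @return An object of class `site_params`.
#' @export
site_params <- function(cf, threshold, bw10, bw40, onset_latency,
                        peak_latency, end_of_peak, spontaneous_rate,
                        depth, peak_driven_rate) {
  if (!(bw10 > 0) || bw40 < bw10) stop("need bw40 >= bw10 > 0")
  if (!(onset_latency < peak_latency && peak_latency < end_of_peak)) {
    stop("need onset_latency < peak_latency < end_of_peak")
  }
  if (spontaneous_rate < 0) stop("spontaneous_rate must be non-negative")
  structure(
    list(
      cf = cf, threshold = threshold, bw10 = bw10, bw40 = bw40,
      onset_latency = onset_latency, peak_latency = peak_latency,
      end_of_peak = end_of_peak, spontaneous_rate = spontaneous_rate,
      depth = depth, peak_driven_rate = peak_driven_rate
    ),
    class = "site_params"
  )
}

# Draw one site's parameters from the group's configured distributions.
# Thresholds are drawn Normal(mean_threshold, threshold_sd) and quantized to
# the intensity grid step: a threshold between tested intensities is not
# identifiable from grid responses, and nearest-step rounding keeps the
# group mean unbiased. CF is log-uniform over the grid span and mapped
# monotonically to depth (800 um/octave + jitter) to build in tonotopy.
draw_site_params <- function(effects, f_range = c(1000, 32000),
                             db_range = c(0, 75), db_step = 5,
                             threshold_sd = 5, depth_jitter = 150) {
  cf <- 2^runif(1, log2(f_range[1]), log2(f_range[2]))
  thr <- round(rnorm(1, effects$mean_threshold, threshold_sd) / db_step) * db_step
  thr <- min(max(thr, db_range[1]), db_range[2])
  bw10 <- max(0.4, rnorm(1, 1.33, 0.15))
  bw40 <- bw10 + max(0.15, rnorm(1, 0.45, 0.12))
  onset <- max(5, rnorm(1, 8.2, 0.6))
  peak <- onset + max(2, rnorm(1, 5.2, 0.6))
  end <- peak + max(5, rnorm(1, 13.7, 1.5))
  spont <- rgamma(1, shape = 4, rate = 4 / 30)
  depth <- 1000 + 800 * log2(cf / f_range[1]) + rnorm(1, 0, depth_jitter)
  pdr <- rlnorm(1, log(1200) - 0.2^2 / 2, 0.2)
  site_params(cf, thr, bw10, bw40, onset, peak, end, spont, depth, pdr)
}

# Per-token response signatures for one site: multiplicative consonant and
# vowel amplitude factors (lognormal, mean 1) and a small consonant latency
# jitter, which is what makes the tokens mutually discriminable.
draw_token_effects <- function(labels, amp_sd = 0.25, latency_sd = 0.8) {
  n <- length(labels)
  data.frame(
    label = labels,
    consonant_factor = rlnorm(n, -amp_sd^2 / 2, amp_sd),
    vowel_factor = rlnorm(n, -amp_sd^2 / 2, amp_sd),
    latency_jitter = rnorm(n, 0, latency_sd),
    row.names = labels,
    stringsAsFactors = FALSE
  )
}

# Fraction of peak_driven_rate carried by the sustained vowel plateau and
# by burst transients.
VOWEL_PLATEAU_FRACTION <- 0.10
BURST_AMPLITUDE_FRACTION <- 0.80

#' Instantaneous firing-rate profile for a stimulus
#'
#' Builds the rate function rate(t) (Hz, t in ms from stimulus onset) a
#' synthetic site produces for a tone, a speech token, or a noise-burst
#' train: spontaneous rate plus a driven component.
#'
#' \itemize{
#'   \item Tones: a raised-cosine transient (onset/peak/end at the site's
#'     latencies) with amplitude `tone_gain * peak_driven_rate * T(f, I)`
#'     where `T` is the site's V-shaped tuning surface (1 at CF at >= 40 dB
#'     above threshold, 0 below threshold or outside the tuning extent).
#'   \item Speech: a consonant transient inside the 0-40 ms window plus a
#'     sustained plateau over the 40-340 ms vowel window, scaled by the
#'     group's speech/consonant/vowel gains (see [group_effect_config()])
#'     and the site's per-token signature.
#'   \item Noise trains: one transient per burst onset, scaled by
#'     `burst_gain`, latencies shifted by the group's burst shifts.
#' }
#'
#' @param stimulus A row of a `tone_grid$stimuli` data frame (or any list
#'   with `frequency` and `intensity`), a row of a [speech_catalog()], or a
#'   [build_noise_train()] object.
#' @param site A [site_params()] object (optionally carrying a
#'   `token_effects` table, as cohort sites do).
#' @param effects A [group_effect_config()] object.
#' @param token_effects Optional per-token signature table (defaults to the
#'   site's, else neutral factors).
#' @return A vectorized function of time (ms) returning Hz, with attributes
#'   `max_rate` (a thinning bound) and `duration` (suggested simulation
#'   span, ms).
#' @export
rate_profile <- function(stimulus, site, effects, token_effects = NULL) {
  if (inherits(stimulus, "noise_train")) {
    return(burst_rate_profile(stimulus, site, effects))
  }
  if (is.list(stimulus) || is.data.frame(stimulus)) {
    if (!is.null(stimulus$frequency) && !is.null(stimulus$intensity)) {
      return(tone_rate_profile(stimulus, site, effects))
    }
    if (!is.null(stimulus$label)) {
      return(speech_rate_profile(stimulus, site, effects, token_effects))
    }
  }
  stop("unrecognized stimulus type: expected a tone, a speech token, or a noise_train")
}

tone_rate_profile <- function(stimulus, site, effects) {
  amp <- effects$tone_gain * site$peak_driven_rate *
    tuning_weight(stimulus$frequency, stimulus$intensity, site)
  spont <- site$spontaneous_rate
  on <- site$onset_latency
  pk <- site$peak_latency
  end <- site$end_of_peak
  fn <- function(t) spont + amp * transient_kernel(t, on, pk, end)
  attr(fn, "max_rate") <- spont + amp
  attr(fn, "duration") <- 50
  fn
}

speech_rate_profile <- function(token, site, effects, token_effects = NULL) {
  if (is.null(token_effects)) token_effects <- site$token_effects
  label <- as.character(token$label)
  if (!is.null(token_effects) && label %in% rownames(token_effects)) {
    fx <- token_effects[label, ]
  } else {
    fx <- list(consonant_factor = 1, vowel_factor = 1, latency_jitter = 0)
  }
  spont <- site$spontaneous_rate
  on <- site$onset_latency + fx$latency_jitter
  pk <- site$peak_latency + fx$latency_jitter
  end <- site$end_of_peak + fx$latency_jitter
  v0 <- token$vowel_start
  v1 <- token$vowel_end
  # Window-shape normalization: speech_gain is the exact whole-window gain;
  # consonant/vowel gains only redistribute the driven integral.
  a_cons0 <- site$peak_driven_rate
  a_vow0 <- VOWEL_PLATEAU_FRACTION * site$peak_driven_rate
  i_cons <- a_cons0 * (site$end_of_peak - site$onset_latency) / 2
  i_vow <- a_vow0 * (v1 - v0)
  eff <- effects$consonant_gain * i_cons + effects$vowel_gain * i_vow
  k <- if (eff > 0) (i_cons + i_vow) / eff else 0
  a_cons <- effects$speech_gain * effects$consonant_gain * k * a_cons0 * fx$consonant_factor
  a_vow <- effects$speech_gain * effects$vowel_gain * k * a_vow0 * fx$vowel_factor
  fn <- function(t) {
    spont + a_cons * transient_kernel(t, on, pk, end) +
      a_vow * as.numeric(t >= v0 & t < v1)
  }
  attr(fn, "max_rate") <- spont + a_cons + a_vow
  attr(fn, "duration") <- token$whole_end
  fn
}

burst_rate_profile <- function(train, site, effects) {
  spont <- site$spontaneous_rate
  on <- max(0.5, site$onset_latency + effects$burst_onset_shift)
  pk <- site$peak_latency + effects$burst_peak_shift
  if (pk <= on) pk <- on + 1
  end <- max(pk + 2, site$end_of_peak + effects$burst_peak_shift)
  amp <- effects$burst_gain * BURST_AMPLITUDE_FRACTION * site$peak_driven_rate
  onsets <- train$onsets
  fn <- function(t) {
    r <- rep(spont, length(t))
    for (o in onsets) {
      r <- r + amp * transient_kernel(t, o + on, o + pk, o + end)
    }
    r
  }
  attr(fn, "max_rate") <- spont + amp
  attr(fn, "duration") <- max(onsets) + train$period
  fn
}

#' Simulate spike trains from a rate function
#'
#' Draws independent inhomogeneous-Poisson realizations over (0, duration]
#' by thinning a homogeneous process at the rate function's maximum.
#'
#' @param rate_fn Vectorized rate function of time (ms) returning Hz,
#'   non-negative on the window. If it carries a `max_rate` attribute (as
#'   [rate_profile()] results do) that is used as the thinning bound;
#'   otherwise the bound is taken from a dense grid evaluation with a 5\%
#'   safety margin.
#' @param duration Trial duration, ms.
#' @param n_repeats Number of independent trials.
#' @param rng_seed Optional integer seed (set before drawing).
#' @return List of `n_repeats` sorted numeric vectors of spike times (ms).
#' @export
simulate_trials <- function(rate_fn, duration, n_repeats, rng_seed = NULL) {
  if (!(n_repeats >= 1)) stop("n_repeats must be at least 1")
  if (!(duration > 0)) stop("duration must be positive")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  max_rate <- attr(rate_fn, "max_rate")
  if (is.null(max_rate)) {
    grid <- seq(0, duration, by = 0.1)
    vals <- rate_fn(grid)
    if (any(vals < 0)) stop("negative rate encountered in rate_fn")
    max_rate <- max(vals) * 1.05
  }
  if (max_rate <= 0) {
    return(replicate(n_repeats, numeric(0), simplify = FALSE))
  }
  counts <- rpois(n_repeats, max_rate * duration / 1000)
  total <- sum(counts)
  if (total == 0) {
    return(replicate(n_repeats, numeric(0), simplify = FALSE))
  }
  times <- runif(total, 0, duration)
  rates <- rate_fn(times)
  if (any(rates < 0)) stop("negative rate encountered in rate_fn")
  keep <- runif(total) * max_rate < rates
  idx <- rep.int(seq_len(n_repeats), counts)
  out <- split(times[keep], factor(idx[keep], levels = seq_len(n_repeats)))
  lapply(unname(out), sort)
}

# Vectorized simulation of single-presentation responses to every tone of a
# grid (one thinning pass over all tones at once; per-tone looping would
# dominate cohort generation time).
simulate_tone_grid_responses <- function(site, grid, effects, duration = 50) {
  st <- grid$stimuli
  amps <- effects$tone_gain * site$peak_driven_rate *
    tuning_weight(st$frequency, st$intensity, site)
  spont <- site$spontaneous_rate
  max_rates <- spont + amps
  counts <- rpois(nrow(st), max_rates * duration / 1000)
  idx <- rep.int(seq_len(nrow(st)), counts)
  tt <- runif(length(idx), 0, duration)
  rates <- spont + amps[idx] *
    transient_kernel(tt, site$onset_latency, site$peak_latency, site$end_of_peak)
  keep <- runif(length(idx)) * max_rates[idx] < rates
  sp <- split(tt[keep], factor(idx[keep], levels = seq_len(nrow(st))))
  out <- lapply(unname(sp), function(v) list(sort(v)))
  names(out) <- st$stimulus_id
  out
}

#' Generate a synthetic multi-group cohort
#'
#' Simulates multiunit recording sites for the configured groups: site
#' parameters are drawn from the group's distributions (CF log-uniform over
#' the grid span, mapped monotonically to depth; thresholds normal about the
#' group mean and quantized to the intensity step), then responses are
#' simulated for every requested stimulus set: one presentation per grid
#' tone, `n_repeats` per speech token, 20 repeats of the noise train, and a
#' block of stimulus-free trials used for spontaneous-rate estimation.
#'
#' Each site runs on its own RNG stream derived deterministically from
#' `(seed, site index)`, so a cohort regenerates identically for the same
#' configuration and seed.
#'
#' @param config Named list of [group_effect_config()] objects; all four
#'   groups of [ic_groups()] must be present.
#' @param grid Optional [build_tone_grid()]; when `NULL` no tone responses
#'   are simulated.
#' @param speech Optional [speech_catalog()]; when `NULL` no speech
#'   responses are simulated.
#' @param train Optional [build_noise_train()]; when `NULL` no burst
#'   responses are simulated.
#' @param seed Integer master seed.
#' @param groups Groups to actually generate (defaults to all configured);
#'   lets callers build single-group cohorts without relaxing the
#'   four-group configuration contract.
#' @param n_spont_trials,spont_duration Stimulus-free block: number of
#'   trials and their duration (ms).
#' @param n_burst_repeats Repeats of the noise train.
#' @return An object of class `ic_cohort`: list with `sites` (named list;
#'   each site has `site_id`, `group`, `animal_id`, `depth`, `params`,
#'   `token_effects`, `responses`), `config`, `seed` and `stimuli`.
#' @export
generate_cohort <- function(config, grid = NULL, speech = NULL, train = NULL,
                            seed = 1L, groups = NULL,
                            n_spont_trials = 20, spont_duration = 400,
                            n_burst_repeats = 20) {
  missing_groups <- setdiff(IC_GROUPS, names(config))
  if (length(missing_groups)) {
    stop("missing group configuration: ", paste(missing_groups, collapse = ", "))
  }
  if (is.null(groups)) groups <- IC_GROUPS
  groups <- match.arg(groups, IC_GROUPS, several.ok = TRUE)
  sites <- list()
  counter <- 0L
  for (g in groups) {
    eff <- config[[g]]
    for (i in seq_len(eff$n_sites)) {
      counter <- counter + 1L
      site_seed <- as.integer(
        (as.numeric(seed) * 2654435 + as.numeric(counter) * 97561) %% 2147483647
      )
      set.seed(site_seed)
      params <- draw_site_params(eff)
      site <- c(params, list(
        site_id = sprintf("%s_%04d", g, i),
        group = g,
        animal_id = sprintf("%s_rat%02d", g, ((i - 1L) %% eff$n_animals) + 1L),
        token_effects = if (!is.null(speech)) draw_token_effects(speech$label) else NULL
      ))
      responses <- list()
      spont_fn <- local({
        r <- params$spontaneous_rate
        f <- function(t) rep(r, length(t))
        attr(f, "max_rate") <- r
        f
      })
      responses$spont <- simulate_trials(spont_fn, spont_duration, n_spont_trials)
      if (!is.null(grid)) {
        responses <- c(responses, simulate_tone_grid_responses(site, grid, eff))
      }
      if (!is.null(speech)) {
        for (k in seq_len(nrow(speech))) {
          tok <- speech[k, ]
          fn <- speech_rate_profile(tok, site, eff, site$token_effects)
          responses[[paste0("speech_", tok$label)]] <-
            simulate_trials(fn, tok$whole_end, tok$n_repeats)
        }
      }
      if (!is.null(train)) {
        fn <- burst_rate_profile(train, site, eff)
        responses$burst_train <-
          simulate_trials(fn, attr(fn, "duration"), n_burst_repeats)
      }
      site$responses <- responses
      sites[[site$site_id]] <- site
    }
  }
  structure(
    list(
      sites = sites, config = config, seed = as.integer(seed),
      stimuli = list(
        grid = grid, speech = speech, train = train,
        spont = list(duration = spont_duration, n_trials = n_spont_trials)
      )
    ),
    class = "ic_cohort"
  )
}

#' @export
print.ic_cohort <- function(x, ...) {
  groups <- vapply(x$sites, `[[`, character(1), "group")
  tab <- table(factor(groups, levels = IC_GROUPS))
  cat(sprintf("Synthetic IC cohort: %d sites (seed %d)\n", length(x$sites), x$seed))
  for (g in names(tab)) if (tab[[g]] > 0) cat(sprintf("  %-15s %4d sites\n", g, tab[[g]]))
  invisible(x)
}

#' Site metadata table for a cohort
#'
#' @param cohort An `ic_cohort`.
#' @return Data frame with one row per site: identifiers, group, depth and
#'   ground-truth site parameters.
#' @export
cohort_sites <- function(cohort) {
  rows <- lapply(cohort$sites, function(s) {
    data.frame(
      site_id = s$site_id, group = s$group, animal_id = s$animal_id,
      depth_um = s$depth, cf = s$cf, threshold = s$threshold,
      bw10 = s$bw10, bw40 = s$bw40, onset_latency = s$onset_latency,
      peak_latency = s$peak_latency, end_of_peak = s$end_of_peak,
      spontaneous_rate = s$spontaneous_rate,
      peak_driven_rate = s$peak_driven_rate,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
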