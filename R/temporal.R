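#' Driven spikes per noise burst
#'
#' Mean over bursts and trials of the spike count in
#' `[onset_k, onset_k + response_window)` minus the expected spontaneous
#' count in that window.
#'
#' @param trials List of spike-time vectors (ms from train onset).
#' @param train A [build_noise_train()] object.
#' @param response_window Per-burst counting window, ms; must not exceed
#'   the inter-burst period (defaults to the full period).
#' @param spontaneous Spontaneous rate, Hz.
#' @return Driven spikes per burst (may be negative under suppression).
#' @export
burst_driven_spikes <- function(trials, train, response_window = NULL,
                                spontaneous = 0) {
  if (!length(trials)) stop("empty trial list")
  if (is.null(response_window)) response_window <- train$period
  if (response_window > train$period + 1e-9) {
    stop("response_window exceeds the inter-burst period (windows would overlap)")
  }
  expected_spont <- spontaneous * response_window / 1000
  per_trial <- vapply(trials, function(tt) {
    mean(vapply(
      train$onsets,
      function(o) sum(tt >= o & tt < o + response_window), numeric(1)
    ))
  }, numeric(1))
  mean(per_trial) - expected_spont
}

#' Vector strength of phase locking
#'
#' Magnitude of the mean resultant of spike phases relative to a period:
#' `VS = (1/n) * sqrt((sum cos theta)^2 + (sum sin theta)^2)` with
#' `theta_i = 2 pi (t_i mod period) / period`. 1 = perfect locking, 0 = no
#' phase preference.
#'
#' @param spike_times Spike times, ms (typically pooled across repeats).
#' @param period Stimulus period, ms.
#' @return Vector strength in `[0, 1]`; `NA` when there are no spikes.
#' @export
vector_strength <- function(spike_times, period) {
  if (!(period > 0)) stop("period must be positive")
  n <- length(spike_times)
  if (n == 0) {
    return(NA_real_)
  }
  theta <- 2 * pi * (spike_times %% period) / period
  sqrt(sum(cos(theta))^2 + sum(sin(theta))^2) / n
}

#' Rayleigh statistic
#'
#' `2 n VS^2`, the Rayleigh test statistic for non-uniformity of spike
#' phases; values above the conventional criterion of 13.8 indicate
#' significant phase locking.
#'
#' @param vs Vector strength in `[0, 1]`.
#' @param n_spikes Number of spikes underlying `vs`.
#' @param criterion Significance criterion (default 13.8).
#' @return The statistic (numeric), with a logical attribute `significant`.
#' @export
rayleigh_statistic <- function(vs, n_spikes, criterion = 13.8) {
  if (is.na(vs)) {
    return(structure(NA_real_, significant = NA))
  }
  if (vs < 0 || vs > 1) stop("vs must lie in [0, 1]")
  if (!(n_spikes >= 1)) stop("n_spikes must be at least 1")
  stat <- 2 * n_spikes * vs^2
  structure(stat, significant = stat > criterion)
}

#' Burst-train response latencies
#'
#' Onset latency is the median across trials of the first spike time after
#' train onset (trials with no spikes are ignored). Peak latency is the
#' center of the maximum-count bin of the first supra-criterion excursion
#' of the pooled 1-ms PSTH (criterion as in [latency_metrics()]).
#'
#' @param trials List of spike-time vectors.
#' @param train A [build_noise_train()] object.
#' @param spontaneous Spontaneous rate, Hz (for the PSTH criterion).
#' @param window PSTH window for the peak search, ms; defaults to the first
#'   inter-burst period.
#' @return Named numeric: `onset`, `peak` (ms; NA when undefined).
#' @export
burst_latencies <- function(trials, train, spontaneous = 0, window = NULL) {
  if (!length(trials)) stop("empty trial list")
  if (is.null(window)) window <- c(0, train$period)
  firsts <- vapply(trials, function(tt) {
    tt <- tt[tt > 0]
    if (length(tt)) min(tt) else NA_real_
  }, numeric(1))
  onset <- if (all(is.na(firsts))) NA_real_ else median(firsts, na.rm = TRUE)
  psth <- compute_psth(trials, bin = 1, window = window)
  peak <- latency_metrics(psth, spontaneous)[["peak"]]
  c(onset = onset, peak = peak)
}

#' Full temporal-following metrics for a burst-train response
#'
#' Assembles driven spikes per burst, onset/peak latency, vector strength
#' of spikes pooled across repeats over the train span (phase referenced
#' to the inter-burst period), and the Rayleigh statistic.
#'
#' @param trials List of spike-time vectors (one per repeat).
#' @param train A [build_noise_train()] object.
#' @param spontaneous Spontaneous rate, Hz.
#' @param response_window Per-burst counting window, ms.
#' @return List of class `temporal_metrics`: `driven_spikes_per_burst`,
#'   `onset_latency`, `peak_latency`, `vector_strength`, `rayleigh`,
#'   `rayleigh_significant`, `n_spikes`.
#' @export
temporal_metrics <- function(trials, train, spontaneous = 0,
                             response_window = NULL) {
  if (is.null(response_window)) response_window <- train$period
  span <- c(0, max(train$onsets) + train$period)
  pooled <- unlist(trials, use.names = FALSE)
  pooled <- pooled[pooled > span[1] & pooled <= span[2]]
  vs <- vector_strength(pooled, train$period)
  ray <- rayleigh_statistic(vs, max(1, length(pooled)))
  lat <- burst_latencies(trials, train, spontaneous)
  structure(
    list(
      driven_spikes_per_burst =
        burst_driven_spikes(trials, train, response_window, spontaneous),
      onset_latency = lat[["onset"]],
      peak_latency = lat[["peak"]],
      vector_strength = vs,
      rayleigh = as.numeric(ray),
      rayleigh_significant = attr(ray, "significant"),
      n_spikes = length(pooled)
    ),
    class = "temporal_metrics"
  )
}
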