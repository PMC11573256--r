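# Count spikes inside a window. PSTHs and driven-rate windows use the
# left-closed convention [a, b); the tone response window uses the
# right-closed convention (0, 32] so a spike exactly at stimulus onset is
# excluded. Both are fixed here so counts are bit-reproducible.
count_in_window <- function(times, window, closed = c("left", "right")) {
  closed <- match.arg(closed)
  if (closed == "left") {
    sum(times >= window[1] & times < window[2])
  } else {
    sum(times > window[1] & times <= window[2])
  }
}

#' Peristimulus time histogram
#'
#' Bins spike times pooled over trials into half-open bins `[t, t+bin)`
#' covering `window`; a spike exactly at the window end is excluded.
#'
#' @param trials List of numeric vectors of spike times (ms from stimulus
#'   onset), one per trial. Must be non-empty (empty trials are allowed and
#'   counted in `n_trials`).
#' @param bin Bin width, ms.
#' @param window Length-2 numeric `(start, end)` in ms; the width must be an
#'   integer multiple of `bin`.
#' @return An object of class `psth`: list with `bin_edges` (ms), `counts`
#'   (pooled spike counts per bin), `n_trials`, and `rate` (Hz,
#'   `counts / (n_trials * bin_width_s)`).
#' @export
compute_psth <- function(trials, bin = 1, window) {
  if (!length(trials)) stop("empty trial list")
  if (!(bin > 0)) stop("bin must be positive")
  width <- window[2] - window[1]
  if (!(width > 0)) stop("window must be nonempty")
  n_bins <- round(width / bin)
  if (abs(width - n_bins * bin) > 1e-9) {
    stop(sprintf("window width %g ms is not divisible by bin %g ms", width, bin))
  }
  tt <- unlist(trials, use.names = FALSE)
  tt <- tt[tt >= window[1] & tt < window[2]]
  counts <- tabulate(floor((tt - window[1]) / bin) + 1L, nbins = n_bins)
  n_trials <- length(trials)
  structure(
    list(
      bin_edges = window[1] + (0:n_bins) * bin,
      counts = counts,
      n_trials = n_trials,
      rate = counts / (n_trials * bin / 1000)
    ),
    class = "psth"
  )
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf(
    "PSTH: %d bins of %g ms over [%g, %g) ms, %d trials, %d spikes\n",
    length(x$counts), diff(x$bin_edges[1:2]), min(x$bin_edges),
    max(x$bin_edges), x$n_trials, sum(x$counts)
  ))
  invisible(x)
}

#' Driven firing rate over a window
#'
#' Mean in-window spike count per trial divided by the window duration,
#' minus the spontaneous rate. Negative values (suppression below the
#' spontaneous rate) are reported as-is. The window is half-open `[a, b)`.
#'
#' @param trials List of spike-time vectors, one per trial.
#' @param window Length-2 numeric, ms.
#' @param spontaneous Spontaneous rate to subtract, Hz.
#' @return Driven rate, Hz.
#' @examples
#' trials <- replicate(20, c(5, 10, 100, 200, 250, 300, 320, 390), simplify = FALSE)
#' driven_rate(trials, c(0, 400), spontaneous = 0) # 8 spikes / 0.4 s = 20 Hz
#' @export
driven_rate <- function(trials, window, spontaneous = 0) {
  if (!length(trials)) stop("empty trial list")
  width_s <- (window[2] - window[1]) / 1000
  if (!(width_s > 0)) stop("window width must be positive")
  if (spontaneous < 0) stop("spontaneous must be non-negative")
  counts <- vapply(trials, count_in_window, numeric(1), window = window)
  mean(counts) / width_s - spontaneous
}

#' Spontaneous firing rate from stimulus-free trials
#'
#' @param pre_stimulus_trials List of spike-time vectors recorded with no
#'   stimulus (or pre-stimulus windows), one per trial.
#' @param window Length-2 numeric, ms, within the recorded span.
#' @return Mean rate, Hz.
#' @export
spontaneous_rate_estimate <- function(pre_stimulus_trials, window) {
  if (!length(pre_stimulus_trials)) stop("empty trial list")
  width_s <- (window[2] - window[1]) / 1000
  if (width_s == 0) stop("zero-duration window")
  counts <- vapply(pre_stimulus_trials, count_in_window, numeric(1), window = window)
  mean(counts) / width_s
}

#' Tone response strength (spikes per tone)
#'
#' Mean spike count in the (0, 32] ms window following tone onset, averaged
#' over all presentations of all grid tones (each grid tone is presented
#' once per site). Optionally restricted to a subset of stimuli (e.g. tones
#' inside the receptive field).
#'
#' @param responses Named list of per-stimulus trial lists (a cohort site's
#'   `responses`), keyed by stimulus id.
#' @param grid A [build_tone_grid()] object.
#' @param window Counting window, ms; spikes in `(window[1], window[2]]`.
#' @param stimulus_ids Optional subset of grid stimulus ids to average over.
#' @return Mean spikes per tone presentation.
#' @export
tone_response_strength <- function(responses, grid, window = c(0, 32),
                                   stimulus_ids = NULL) {
  ids <- if (is.null(stimulus_ids)) grid$stimuli$stimulus_id else stimulus_ids
  missing <- setdiff(ids, names(responses))
  if (length(missing)) {
    stop(
      "missing tone responses for ", length(missing), " stimuli (first: ",
      missing[1], ")"
    )
  }
  counts <- unlist(lapply(ids, function(id) {
    vapply(responses[[id]], count_in_window, numeric(1),
      window = window, closed = "right"
    )
  }), use.names = FALSE)
  mean(counts)
}
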