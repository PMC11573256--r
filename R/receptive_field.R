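# 3x3 running median with replicate padding at matrix edges (a truncated
# window would be biased there: with only 6 cells, half of them driven, the
# median of an edge row adjacent to the response area turns supra-criterion).
median_filter_3x3 <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  pad <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  out <- m
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      out[i, j] <- median(pad[i:(i + 2), j:(j + 2)])
    }
  }
  out
}

#' Build a frequency response area from grid responses
#'
#' Assembles the (frequency x intensity) matrix of mean spike counts in the
#' (0, 32] ms tone window from a site's responses to every grid tone.
#'
#' @param responses Named list of per-stimulus trial lists keyed by the
#'   grid's stimulus ids.
#' @param grid A [build_tone_grid()] object.
#' @param window Counting window, ms (right-closed).
#' @return An object of class `fra`: list with `counts` (matrix, rows =
#'   frequencies, cols = intensities), `frequencies`, `intensities`,
#'   `window`.
#' @export
build_fra <- function(responses, grid, window = c(0, 32)) {
  st <- grid$stimuli
  missing <- setdiff(st$stimulus_id, names(responses))
  if (length(missing)) {
    miss <- st[st$stimulus_id %in% missing, ]
    stop(
      "missing tone responses for ", length(missing),
      " (frequency, intensity) pairs, first: (",
      miss$frequency[1], " Hz, ", miss$intensity[1], " dB)"
    )
  }
  cnt <- vapply(st$stimulus_id, function(id) {
    trials <- responses[[id]]
    mean(vapply(trials, count_in_window, numeric(1),
      window = window, closed = "right"
    ))
  }, numeric(1))
  counts <- matrix(cnt,
    nrow = length(grid$frequencies),
    dimnames = list(
      signif(grid$frequencies, 6),
      grid$intensities
    )
  )
  structure(
    list(
      counts = counts, frequencies = grid$frequencies,
      intensities = grid$intensities, window = window
    ),
    class = "fra"
  )
}

# Runs of supra-criterion frequencies in one intensity row.
supra_runs <- function(row_vals, crit) {
  r <- rle(row_vals > crit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(
    start = starts[r$values], end = ends[r$values],
    length = r$lengths[r$values]
  )
}

#' Extract receptive-field properties from an FRA
#'
#' Standard frequency-response-area characterization: the count matrix is
#' smoothed with a 3x3 median filter; the response criterion is the
#' expected spontaneous count in the FRA window plus
#' `max(criterion_floor, criterion_frac * (smoothed max - spontaneous
#' count))`; the threshold is the lowest intensity whose row contains a run
#' of at least `min_run` adjacent supra-criterion frequencies; CF is the
#' geometric-mean frequency of that run; BW10/BW40 are the octave extents
#' of the supra-criterion run at threshold + 10/40 dB (NA when that
#' intensity exceeds the grid maximum). A site with no qualifying intensity
#' is marked unresponsive (all properties NA), not an error.
#'
#' The exact smoothing and criterion constants differ between labs, so all
#' are arguments.
#'
#' @param fra A [build_fra()] object.
#' @param spontaneous Spontaneous rate, Hz (converted to an expected count
#'   over the FRA window).
#' @param criterion_frac Fraction of the above-spontaneous dynamic range.
#' @param criterion_floor Minimum criterion elevation, spikes.
#' @param min_run Minimum adjacent supra-criterion frequencies.
#' @param smooth Apply the 3x3 median filter (disable for noiseless input).
#' @return An object of class `receptive_field`: list with `cf` (Hz),
#'   `threshold` (dB SPL), `bw10`, `bw40` (octaves), `onset_latency`,
#'   `peak_latency`, `end_of_peak` (ms; filled by
#'   [site_receptive_field()]), `spontaneous_rate` (Hz), `responsive`.
#' @export
extract_rf <- function(fra, spontaneous, criterion_frac = 0.2,
                       criterion_floor = 1, min_run = 2, smooth = TRUE) {
  m <- if (smooth) median_filter_3x3(fra$counts) else fra$counts
  spont_count <- spontaneous * (fra$window[2] - fra$window[1]) / 1000
  crit <- spont_count +
    max(criterion_floor, criterion_frac * (max(m) - spont_count))
  empty_rf <- structure(
    list(
      cf = NA_real_, threshold = NA_real_, bw10 = NA_real_, bw40 = NA_real_,
      onset_latency = NA_real_, peak_latency = NA_real_,
      end_of_peak = NA_real_, spontaneous_rate = spontaneous,
      responsive = FALSE, criterion = crit
    ),
    class = "receptive_field"
  )
  freqs <- fra$frequencies
  ints <- fra$intensities
  thr_idx <- NA_integer_
  thr_run <- NULL
  for (j in seq_along(ints)) {
    runs <- supra_runs(m[, j], crit)
    runs <- runs[runs$length >= min_run, , drop = FALSE]
    if (nrow(runs)) {
      thr_idx <- j
      # pick the most responsive run when several qualify
      sums <- vapply(
        seq_len(nrow(runs)),
        function(k) sum(m[runs$start[k]:runs$end[k], j]), numeric(1)
      )
      thr_run <- runs[which.max(sums), ]
      break
    }
  }
  if (is.na(thr_idx)) {
    return(empty_rf)
  }
  threshold <- ints[thr_idx]
  cf <- 2^mean(log2(freqs[thr_run$start:thr_run$end]))
  bw_at <- function(level) {
    target <- threshold + level
    j <- match(target, ints)
    if (is.na(j)) {
      return(NA_real_)
    }
    runs <- supra_runs(m[, j], crit)
    runs <- runs[runs$length >= min_run, , drop = FALSE]
    if (!nrow(runs)) {
      return(NA_real_)
    }
    # run whose center is nearest CF
    centers <- vapply(
      seq_len(nrow(runs)),
      function(k) mean(log2(freqs[c(runs$start[k], runs$end[k])])), numeric(1)
    )
    k <- which.min(abs(centers - log2(cf)))
    log2(freqs[runs$end[k]] / freqs[runs$start[k]])
  }
  structure(
    list(
      cf = cf, threshold = threshold, bw10 = bw_at(10), bw40 = bw_at(40),
      onset_latency = NA_real_, peak_latency = NA_real_,
      end_of_peak = NA_real_, spontaneous_rate = spontaneous,
      responsive = TRUE, criterion = crit
    ),
    class = "receptive_field"
  )
}

#' @export
print.receptive_field <- function(x, ...) {
  if (!x$responsive) {
    cat("Receptive field: unresponsive site\n")
  } else {
    cat(sprintf(
      "Receptive field: CF %.2f kHz, threshold %g dB, BW10 %.2f oct, BW40 %.2f oct\n",
      x$cf / 1000, x$threshold, x$bw10, x$bw40
    ))
    if (!is.na(x$onset_latency)) {
      cat(sprintf(
        "  latencies (ms): onset %.1f, peak %.1f, end of peak %.1f\n",
        x$onset_latency, x$peak_latency, x$end_of_peak
      ))
    }
  }
  invisible(x)
}

#' Response latencies from a PSTH
#'
#' Criterion-crossing latency extraction on a 1-ms PSTH: the criterion is
#' the expected pooled spontaneous count per bin plus twice the SD of the
#' spontaneous count distribution (Poisson, `sqrt(m)`, unless a sample SD
#' is supplied). Onset is the left edge of the first run of at least
#' `min_run` consecutive supra-criterion bins; peak is the center of the
#' maximum-count bin of that first excursion; end-of-peak is the left edge
#' of the first bin after the excursion falls back below criterion. All
#' three are NA when no excursion exists.
#'
#' @param psth A [compute_psth()] object (1-ms bins recommended).
#' @param spontaneous Spontaneous rate, Hz.
#' @param spont_sd_count Optional SD of the pooled per-bin spontaneous
#'   count (overrides the Poisson value).
#' @param min_run Minimum consecutive supra-criterion bins.
#' @return Named numeric: `onset`, `peak`, `end_of_peak` (ms).
#' @export
latency_metrics <- function(psth, spontaneous, spont_sd_count = NULL,
                            min_run = 2) {
  binw <- diff(psth$bin_edges[1:2])
  m <- spontaneous * binw / 1000 * psth$n_trials
  sdv <- if (is.null(spont_sd_count)) sqrt(m) else spont_sd_count
  crit <- m + 2 * sdv
  supra <- psth$counts > crit
  undefined <- c(onset = NA_real_, peak = NA_real_, end_of_peak = NA_real_)
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_run)
  if (!length(ok)) {
    return(undefined)
  }
  s <- starts[ok[1]]
  e <- ends[ok[1]]
  peak_idx <- s + which.max(psth$counts[s:e]) - 1L
  end_of_peak <- if (e < length(psth$counts)) psth$bin_edges[e + 1L] else NA_real_
  c(
    onset = psth$bin_edges[s],
    peak = psth$bin_edges[peak_idx] + binw / 2,
    end_of_peak = end_of_peak
  )
}

#' Full receptive-field characterization of a cohort site
#'
#' Convenience wrapper: estimates the spontaneous rate from the site's
#' stimulus-free trials, builds the FRA, extracts threshold/CF/bandwidths,
#' and fills in latencies from a pooled 1-ms PSTH of the tones inside the
#' receptive field (intensity at or above threshold, frequency within
#' BW10/2 of CF).
#'
#' @param site A cohort site (list with `responses`).
#' @param grid The [build_tone_grid()] the responses were recorded to.
#' @param spontaneous Optional spontaneous rate, Hz; estimated from the
#'   site's `spont` trials when NULL.
#' @param latency_window PSTH window for latency extraction, ms.
#' @param ... Passed to [extract_rf()].
#' @return A `receptive_field` object with latencies filled when defined.
#' @export
site_receptive_field <- function(site, grid, spontaneous = NULL,
                                 latency_window = c(0, 40), ...) {
  if (is.null(spontaneous)) {
    spontaneous <- if (!is.null(site$responses$spont)) {
      spontaneous_rate_estimate(site$responses$spont, c(0, 400))
    } else {
      0
    }
  }
  fra <- build_fra(site$responses, grid)
  rf <- extract_rf(fra, spontaneous, ...)
  if (!rf$responsive) {
    return(rf)
  }
  half_bw <- if (is.na(rf$bw10)) 0.5 else rf$bw10 / 2
  st <- grid$stimuli
  sel <- st$intensity >= rf$threshold &
    abs(log2(st$frequency / rf$cf)) <= half_bw
  ids <- st$stimulus_id[sel]
  if (length(ids)) {
    pooled <- unlist(lapply(site$responses[ids], identity), recursive = FALSE)
    psth <- compute_psth(pooled, bin = 1, window = latency_window)
    lat <- latency_metrics(psth, spontaneous)
    rf$onset_latency <- lat[["onset"]]
    rf$peak_latency <- lat[["peak"]]
    rf$end_of_peak <- lat[["end_of_peak"]]
  }
  rf
}

#' Tonotopy summary for a group of sites
#'
#' Spearman correlation between log2 characteristic frequency and recording
#' depth, plus the percentage of responsive sites per 1-octave frequency
#' bin over 1-32 kHz.
#'
#' @param cf Characteristic frequencies, Hz (responsive sites only).
#' @param depth Recording depths, micrometers (same length).
#' @param f_lo Lower edge of the first octave bin, Hz.
#' @param n_octaves Number of 1-octave bins.
#' @return List with `correlation` (Spearman rho of log2(cf) vs depth) and
#'   `percent_per_octave` (named vector summing to 100).
#' @export
tonotopy_summary <- function(cf, depth, f_lo = 1000, n_octaves = 5) {
  keep <- !is.na(cf) & !is.na(depth)
  cf <- cf[keep]
  depth <- depth[keep]
  if (length(cf) < 3) stop("too few responsive sites with depth (need >= 3)")
  if (length(cf) != length(depth)) stop("cf and depth lengths differ")
  rho <- cor(log2(cf), depth, method = "spearman")
  oct <- log2(cf / f_lo)
  bin <- pmin(floor(oct), n_octaves - 1) + 1 # top edge closed
  bin <- pmax(bin, 1)
  counts <- tabulate(bin, nbins = n_octaves)
  edges <- f_lo * 2^(0:n_octaves)
  names(counts) <- sprintf(
    "%g-%g kHz", edges[-length(edges)] / 1000, edges[-1] / 1000
  )
  list(
    correlation = rho,
    percent_per_octave = 100 * counts / length(cf)
  )
}
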