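#' Build a logarithmic tone search grid
#'
#' Constructs the pure-tone frequency x intensity grid used for
#' frequency-response-area mapping: frequencies from `f_lo` to `f_hi` in
#' steps of `octave_step` octaves (equally spaced in log2), crossed with
#' intensities from `db_lo` to `db_hi` in steps of `db_step` dB SPL. The
#' default tone is 25 ms long with 5-ms cosine ramps.
#'
#' The standard search grid in this package spans 1-32 kHz in 0.0625-octave
#' steps at 0-75 dB SPL in 5-dB steps: 81 frequencies x 16 intensities =
#' 1,296 tones, each presented once per site.
#'
#' @param f_lo,f_hi Lowest and highest frequency, Hz. `log2(f_hi/f_lo)` must
#'   be an integer multiple of `octave_step` (tolerance 1e-6 octaves).
#' @param octave_step Frequency step, octaves.
#' @param db_lo,db_hi Lowest and highest intensity, dB SPL. The span must be
#'   an integer multiple of `db_step`.
#' @param db_step Intensity step, dB.
#' @param duration Tone duration, ms.
#' @param ramp Cosine on/off ramp, ms; `2 * ramp` must not exceed `duration`.
#' @return An object of class `tone_grid`: a list with `frequencies` (Hz),
#'   `intensities` (dB SPL) and `stimuli`, a data frame with one row per
#'   (frequency, intensity) combination (`stimulus_id`, `frequency`,
#'   `intensity`, `duration`, `ramp`). Frequency varies fastest.
#' @examples
#' grid <- build_tone_grid(1000, 32000, 0.0625, 0, 75, 5)
#' nrow(grid$stimuli) # 1296
#' @export
build_tone_grid <- function(f_lo, f_hi, octave_step, db_lo, db_hi, db_step,
                            duration = 25, ramp = 5) {
  if (!(f_lo > 0) || !(f_hi > f_lo)) {
    stop("empty frequency range: need 0 < f_lo < f_hi")
  }
  if (octave_step <= 0 || db_step <= 0) {
    stop("octave_step and db_step must be positive")
  }
  if (db_lo > db_hi) stop("empty intensity range: db_lo > db_hi")
  if (ramp < 0 || 2 * ramp > duration) {
    stop("invalid tone envelope: need ramp >= 0 and 2*ramp <= duration")
  }
  span <- log2(f_hi / f_lo)
  n_f <- round(span / octave_step)
  resid <- abs(span - n_f * octave_step)
  if (resid > 1e-6) {
    stop(sprintf(
      "frequency span %.6f octaves is not divisible by octave_step = %g (residual %.3g octaves)",
      span, octave_step, resid
    ))
  }
  db_span <- db_hi - db_lo
  n_i <- round(db_span / db_step)
  if (abs(db_span - n_i * db_step) > 1e-9) {
    stop(sprintf(
      "intensity span %g dB is not divisible by db_step = %g dB (residual %g dB)",
      db_span, db_step, db_span - n_i * db_step
    ))
  }
  frequencies <- f_lo * 2^((0:n_f) * octave_step)
  frequencies[length(frequencies)] <- f_hi # exact endpoint
  intensities <- db_lo + (0:n_i) * db_step
  combo <- expand.grid(
    frequency = frequencies, intensity = intensities,
    KEEP.OUT.ATTRS = FALSE
  )
  stimuli <- data.frame(
    stimulus_id = sprintf("tone_%04d", seq_len(nrow(combo))),
    frequency = combo$frequency,
    intensity = combo$intensity,
    duration = duration,
    ramp = ramp,
    stringsAsFactors = FALSE
  )
  structure(
    list(frequencies = frequencies, intensities = intensities, stimuli = stimuli),
    class = "tone_grid"
  )
}

#' @export
print.tone_grid <- function(x, ...) {
  cat(sprintf(
    "Tone grid: %d frequencies (%.3g-%.3g kHz) x %d intensities (%g-%g dB SPL), %d stimuli\n",
    length(x$frequencies), min(x$frequencies) / 1000, max(x$frequencies) / 1000,
    length(x$intensities), min(x$intensities), max(x$intensities), nrow(x$stimuli)
  ))
  invisible(x)
}

#' VNS-paired multi-tone set
#'
#' The seven tones paired with vagus nerve stimulation in the multi-tone
#' pairing protocol: frequencies spanning the rat hearing range (1.3, 2.2,
#' 3.7, 6.3, 10.6, 17.8, 29.9 kHz) with intensities following the contour of
#' the rat audiogram (55, 50, 40, 35, 35, 45, 55 dB SPL, respectively).
#'
#' @param duration Tone duration, ms.
#' @param ramp Cosine ramp, ms.
#' @return Data frame with one row per tone (`stimulus_id`, `frequency` Hz,
#'   `intensity` dB SPL, `duration`, `ramp`).
#' @export
build_paired_tone_set <- function(duration = 25, ramp = 5) {
  freq_khz <- c(1.3, 2.2, 3.7, 6.3, 10.6, 17.8, 29.9)
  db <- c(55, 50, 40, 35, 35, 45, 55)
  data.frame(
    stimulus_id = sprintf("paired_tone_%d", seq_along(freq_khz)),
    frequency = freq_khz * 1000,
    intensity = db,
    duration = duration,
    ramp = ramp,
    stringsAsFactors = FALSE
  )
}

#' Periodic noise-burst train
#'
#' A train of `n_bursts` white-noise bursts presented at `rate` Hz; burst
#' onsets form the arithmetic sequence 0, 1000/rate, ..., in ms. The
#' standard train is six 25-ms bursts at 10 Hz (onsets 0, 100, ..., 500 ms).
#'
#' @param rate Repetition rate, Hz.
#' @param n_bursts Number of bursts (>= 1).
#' @param burst_duration Duration of each burst, ms.
#' @return An object of class `noise_train`: list with `n_bursts`, `rate`,
#'   `burst_duration`, `onsets` (ms) and `period` (ms).
#' @examples
#' build_noise_train(10, 6, 25)$onsets # 0 100 200 300 400 500
#' @export
build_noise_train <- function(rate = 10, n_bursts = 6, burst_duration = 25) {
  if (!(rate > 0)) stop("rate must be positive")
  if (!(n_bursts >= 1)) stop("n_bursts must be at least 1")
  if (!(burst_duration > 0)) stop("burst_duration must be positive")
  period <- 1000 / rate
  if (burst_duration > period) stop("burst_duration exceeds the inter-burst period")
  structure(
    list(
      n_bursts = as.integer(n_bursts), rate = rate,
      burst_duration = burst_duration,
      onsets = (seq_len(n_bursts) - 1) * period,
      period = period
    ),
    class = "noise_train"
  )
}

#' @export
print.noise_train <- function(x, ...) {
  cat(sprintf(
    "Noise-burst train: %d x %g-ms bursts at %g Hz (period %g ms)\n",
    x$n_bursts, x$burst_duration, x$rate, x$period
  ))
  invisible(x)
}

SPEECH_TOKENS <- c(
  "chad", "dad", "deed", "dood", "fad", "gad",
  "had", "jad", "sad", "shad", "tad"
)

#' Speech-token catalog with analysis windows
#'
#' The eleven consonant-vowel-consonant speech tokens used as complex
#' stimuli, each presented `n_repeats` times. Every token carries the fixed
#' analysis windows used downstream: consonant = first 40 ms, vowel = the
#' following 300 ms (40-340 ms, beginning at initial-consonant offset), and
#' whole = 0-400 ms, all relative to token onset. The consonant-contrast
#' subset is the nine "-ad" tokens; the vowel-contrast subset is
#' dad / deed / dood.
#'
#' @param n_repeats Repeats per token (default 20).
#' @return An object of class `speech_catalog` (a data frame), one row per
#'   token with window columns in ms.
#' @seealso [consonant_tokens()], [vowel_tokens()]
#' @export
speech_catalog <- function(n_repeats = 20) {
  out <- data.frame(
    label = SPEECH_TOKENS,
    consonant_start = 0, consonant_end = 40,
    vowel_start = 40, vowel_end = 340,
    whole_start = 0, whole_end = 400,
    n_repeats = as.integer(n_repeats),
    stringsAsFactors = FALSE
  )
  class(out) <- c("speech_catalog", "data.frame")
  out
}

#' Consonant-contrast token subset
#'
#' The nine tokens sharing the "-ad" vowel and differing only in initial
#' consonant (chad, dad, fad, gad, had, jad, sad, shad, tad).
#'
#' @param catalog A [speech_catalog()].
#' @return Character vector of token labels, sorted.
#' @export
consonant_tokens <- function(catalog = speech_catalog()) {
  sort(grep("ad$", catalog$label, value = TRUE))
}

#' Vowel-contrast token subset
#'
#' The three tokens sharing the initial consonant and differing in vowel
#' (dad, deed, dood).
#'
#' @param catalog A [speech_catalog()].
#' @return Character vector of token labels.
#' @export
vowel_tokens <- function(catalog = speech_catalog()) {
  intersect(catalog$label, c("dad", "deed", "dood"))
}

#' Serialize stimulus sets to JSON
#'
#' Writes (or returns) a JSON document describing the stimulus sets with
#' stable key order: tone grid, VNS-paired tone set, noise-burst train and
#' speech catalog.
#'
#' @param grid Optional [build_tone_grid()] result.
#' @param paired_tones Optional [build_paired_tone_set()] result.
#' @param train Optional [build_noise_train()] result.
#' @param catalog Optional [speech_catalog()] result.
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
stimuli_to_json <- function(grid = NULL, paired_tones = NULL, train = NULL,
                            catalog = NULL, path = NULL) {
  doc <- list()
  if (!is.null(grid)) {
    doc$tone_grid <- list(
      frequencies_hz = grid$frequencies,
      intensities_db = grid$intensities,
      duration_ms = grid$stimuli$duration[1],
      ramp_ms = grid$stimuli$ramp[1],
      n_stimuli = nrow(grid$stimuli)
    )
  }
  if (!is.null(paired_tones)) doc$paired_tones <- paired_tones
  if (!is.null(train)) doc$noise_train <- unclass(train)
  if (!is.null(catalog)) doc$speech_catalog <- as.data.frame(catalog)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
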