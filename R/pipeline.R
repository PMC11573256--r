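#' Analysis configuration
#'
#' Bundles every analysis-relevant parameter: windows (ms), PSTH bin,
#' receptive-field extraction constants, classifier settings, statistics
#' family and seeds. The configuration is hashed into report manifests via
#' [config_hash()].
#'
#' @param speech_whole,speech_consonant,speech_vowel Speech driven-rate
#'   windows, ms.
#' @param tone_window Tone response-strength window, ms (right-closed).
#' @param burst_response_window Per-burst counting window, ms.
#' @param psth_bin Default PSTH bin, ms.
#' @param rf Receptive-field extraction knobs (see [extract_rf()]).
#' @param stats_family Family for metric comparisons.
#' @param rf_stats_family Family for receptive-field property comparisons.
#' @param alpha Significance level carried into reports.
#' @param tie_seed,tie_mode,template Classifier settings.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(speech_whole = c(0, 400),
                            speech_consonant = c(0, 40),
                            speech_vowel = c(40, 340),
                            tone_window = c(0, 32),
                            burst_response_window = 100,
                            psth_bin = 1,
                            rf = list(
                              criterion_frac = 0.2, criterion_floor = 1,
                              min_run = 2, smooth = TRUE
                            ),
                            stats_family = "nonparametric",
                            rf_stats_family = "brown_forsythe",
                            alpha = 0.05,
                            tie_seed = 1L, tie_mode = "random",
                            template = "paired") {
  structure(
    list(
      speech_whole = speech_whole, speech_consonant = speech_consonant,
      speech_vowel = speech_vowel, tone_window = tone_window,
      burst_response_window = burst_response_window, psth_bin = psth_bin,
      rf = rf, stats_family = stats_family,
      rf_stats_family = rf_stats_family, alpha = alpha,
      tie_seed = as.integer(tie_seed), tie_mode = tie_mode,
      template = template
    ),
    class = "analysis_config"
  )
}

# Which analysis stages the cohort's responses support.
detect_stages <- function(cohort) {
  resp <- names(cohort$sites[[1]]$responses)
  stages <- character(0)
  if (any(startsWith(resp, "speech_"))) stages <- c(stages, "speech", "classifier")
  if (any(startsWith(resp, "tone_"))) stages <- c(stages, "tones", "rf")
  if ("burst_train" %in% resp) stages <- c(stages, "bursts")
  stages
}

#' Per-site metric table
#'
#' Computes every per-site metric the requested stages support: estimated
#' spontaneous rate; driven firing rates over the whole (0-400 ms),
#' consonant (0-40 ms) and vowel (40-340 ms) speech windows (mean over
#' tokens); classifier consonant/vowel accuracies; tone spikes per tone;
#' receptive-field properties; and burst-train temporal metrics.
#'
#' @param cohort An `ic_cohort`.
#' @param config An [analysis_config()].
#' @param stages Subset of `c("speech", "classifier", "tones", "rf",
#'   "bursts")`; defaults to every stage the cohort supports.
#' @return Data frame, one row per site.
#' @export
site_metrics <- function(cohort, config = analysis_config(), stages = NULL) {
  available <- detect_stages(cohort)
  stages <- if (is.null(stages)) available else intersect(stages, available)
  grid <- cohort$stimuli$grid
  speech <- cohort$stimuli$speech
  train <- cohort$stimuli$train
  spont_window <- c(0, cohort$stimuli$spont$duration)
  rows <- lapply(cohort$sites, function(s) {
    spont <- if (!is.null(s$responses$spont)) {
      spontaneous_rate_estimate(s$responses$spont, spont_window)
    } else {
      0
    }
    row <- data.frame(
      site_id = s$site_id, group = s$group, animal_id = s$animal_id,
      depth_um = s$depth, spontaneous_hz = spont,
      stringsAsFactors = FALSE
    )
    if ("speech" %in% stages) {
      ids <- paste0("speech_", speech$label)
      mean_driven <- function(window) {
        mean(vapply(
          ids,
          function(id) driven_rate(s$responses[[id]], window, spont),
          numeric(1)
        ))
      }
      row$speech_driven_whole <- mean_driven(config$speech_whole)
      row$speech_driven_consonant <- mean_driven(config$speech_consonant)
      row$speech_driven_vowel <- mean_driven(config$speech_vowel)
    }
    if ("classifier" %in% stages) {
      row$classifier_consonant <- consonant_discrimination(
        s, speech,
        tie_seed = config$tie_seed, tie_mode = config$tie_mode,
        template = config$template
      )$mean_accuracy
      row$classifier_vowel <- vowel_discrimination(
        s, speech,
        tie_seed = config$tie_seed, tie_mode = config$tie_mode,
        template = config$template
      )$mean_accuracy
    }
    if ("tones" %in% stages) {
      row$tone_spikes_per_tone <- tone_response_strength(
        s$responses, grid, config$tone_window
      )
    }
    if ("rf" %in% stages) {
      rf <- do.call(site_receptive_field, c(
        list(site = s, grid = grid, spontaneous = spont), config$rf
      ))
      row$rf_responsive <- rf$responsive
      row$rf_cf <- rf$cf
      row$rf_threshold <- rf$threshold
      row$rf_bw10 <- rf$bw10
      row$rf_bw40 <- rf$bw40
      row$rf_onset_latency <- rf$onset_latency
      row$rf_peak_latency <- rf$peak_latency
      row$rf_end_of_peak <- rf$end_of_peak
    }
    if ("bursts" %in% stages) {
      tm <- temporal_metrics(
        s$responses$burst_train, train, spont,
        config$burst_response_window
      )
      row$burst_driven_per_burst <- tm$driven_spikes_per_burst
      row$burst_onset_latency <- tm$onset_latency
      row$burst_peak_latency <- tm$peak_latency
      row$burst_vector_strength <- tm$vector_strength
      row$burst_rayleigh <- tm$rayleigh
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Split a metric column by group, dropping NA and groups that are absent.
metric_by_group <- function(metrics, column) {
  present <- intersect(IC_GROUPS, unique(metrics$group))
  vals <- lapply(present, function(g) {
    x <- metrics[[column]][metrics$group == g]
    x[!is.na(x)]
  })
  names(vals) <- present
  vals[vapply(vals, length, integer(1)) >= 3]
}

safe_compare <- function(values, metric, family) {
  if (length(values) < 2) {
    return(NULL)
  }
  compare_groups(values, metric = metric, family = family)
}

#' Run the full analysis pipeline on a cohort
#'
#' Computes the per-site metric table, then one group-comparison block per
#' figure-level analysis the cohort supports: speech driven rates over the
#' whole/consonant/vowel windows, classifier consonant/vowel accuracies,
#' tone response strength, burst-train metrics (driven spikes per burst,
#' onset/peak latency, vector strength), and a receptive-field property
#' table compared with the Brown-Forsythe family. Percent-change summaries
#' of the whole-window speech driven rate (VNS-tone vs VPA and VNS-speech
#' vs VPA) are included when both groups are present.
#'
#' When `out_dir` is given the report is written as `metrics.csv`,
#' `comparisons.json` and `manifest.json`; on failure partial outputs are
#' removed.
#'
#' @param cohort An `ic_cohort`.
#' @param config An [analysis_config()].
#' @param stages Optional stage subset (see [site_metrics()]).
#' @param out_dir Optional output directory.
#' @return An object of class `ic_report`: list with `metrics`,
#'   `comparisons`, `rf_properties`, `percent_change`, `manifest`.
#' @export
run_full_analysis <- function(cohort, config = analysis_config(),
                              stages = NULL, out_dir = NULL) {
  available <- detect_stages(cohort)
  stages <- if (is.null(stages)) available else intersect(stages, available)
  metrics <- site_metrics(cohort, config, stages)
  fam <- config$stats_family
  comparisons <- list()
  if ("speech" %in% stages) {
    comparisons$speech_driven_whole <- safe_compare(
      metric_by_group(metrics, "speech_driven_whole"),
      "speech driven rate, 0-400 ms (Hz)", fam
    )
    comparisons$speech_driven_consonant <- safe_compare(
      metric_by_group(metrics, "speech_driven_consonant"),
      "speech driven rate, consonant 0-40 ms (Hz)", fam
    )
    comparisons$speech_driven_vowel <- safe_compare(
      metric_by_group(metrics, "speech_driven_vowel"),
      "speech driven rate, vowel 40-340 ms (Hz)", fam
    )
  }
  if ("classifier" %in% stages) {
    comparisons$classifier_consonant <- safe_compare(
      metric_by_group(metrics, "classifier_consonant"),
      "consonant classifier accuracy (%)", fam
    )
    comparisons$classifier_vowel <- safe_compare(
      metric_by_group(metrics, "classifier_vowel"),
      "vowel classifier accuracy (%)", fam
    )
  }
  if ("tones" %in% stages) {
    comparisons$tone_strength <- safe_compare(
      metric_by_group(metrics, "tone_spikes_per_tone"),
      "tone response strength (spikes/tone)", fam
    )
  }
  if ("bursts" %in% stages) {
    comparisons$burst <- list(
      driven = safe_compare(
        metric_by_group(metrics, "burst_driven_per_burst"),
        "driven spikes per noise burst", fam
      ),
      onset_latency = safe_compare(
        metric_by_group(metrics, "burst_onset_latency"),
        "burst onset latency (ms)", fam
      ),
      peak_latency = safe_compare(
        metric_by_group(metrics, "burst_peak_latency"),
        "burst peak latency (ms)", fam
      ),
      vector_strength = safe_compare(
        metric_by_group(metrics, "burst_vector_strength"),
        "vector strength", fam
      )
    )
  }
  rf_properties <- NULL
  if ("rf" %in% stages) {
    rf_cols <- c(
      threshold = "rf_threshold", bw10 = "rf_bw10", bw40 = "rf_bw40",
      onset_latency = "rf_onset_latency", peak_latency = "rf_peak_latency",
      end_of_peak = "rf_end_of_peak", spontaneous_rate = "spontaneous_hz"
    )
    rf_properties <- lapply(names(rf_cols), function(p) {
      safe_compare(
        metric_by_group(metrics, rf_cols[[p]]),
        paste0("RF ", p), config$rf_stats_family
      )
    })
    names(rf_properties) <- names(rf_cols)
  }
  pct <- NULL
  if ("speech" %in% stages) {
    gm <- tapply(metrics$speech_driven_whole, metrics$group, mean, na.rm = TRUE)
    pct <- list()
    if (all(c("vpa", "vpa_vns_tone") %in% names(gm))) {
      pct$vns_tone_vs_vpa <- percent_change(gm[["vpa"]], gm[["vpa_vns_tone"]])
    }
    if (all(c("vpa", "vpa_vns_speech") %in% names(gm))) {
      pct$vns_speech_vs_vpa <- percent_change(gm[["vpa"]], gm[["vpa_vns_speech"]])
    }
    if (!length(pct)) pct <- NULL
  }
  report <- structure(
    list(
      metrics = metrics,
      comparisons = comparisons,
      rf_properties = rf_properties,
      percent_change = pct,
      manifest = list(
        config_hash = config_hash(unclass(config)),
        cohort_seed = cohort$seed,
        stages = stages,
        n_sites = nrow(metrics)
      )
    ),
    class = "ic_report"
  )
  if (!is.null(out_dir)) {
    ok <- FALSE
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    on.exit(if (!ok) {
      unlink(file.path(out_dir, c(
        "metrics.csv",
        "comparisons.json", "manifest.json"
      )))
    })
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(
        comparisons = strip_classes(comparisons),
        rf_properties = strip_classes(rf_properties),
        percent_change = pct
      ),
      file.path(out_dir, "comparisons.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
    )
    jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    ok <- TRUE
  }
  report
}

# Recursively drop S3 classes so jsonlite serializes comparison objects as
# plain structures.
strip_classes <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' @export
print.ic_report <- function(x, ...) {
  cat(sprintf(
    "IC analysis report: %d sites, stages: %s\n",
    x$manifest$n_sites, paste(x$manifest$stages, collapse = ", ")
  ))
  if (!is.null(x$percent_change)) {
    for (nm in names(x$percent_change)) {
      cat(sprintf(
        "  %s: %+.1f%% (whole-window speech driven rate)\n",
        nm, x$percent_change[[nm]]
      ))
    }
  }
  blocks <- names(x$comparisons)
  if (length(blocks)) cat("  comparison blocks:", paste(blocks, collapse = ", "), "\n")
  invisible(x)
}
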