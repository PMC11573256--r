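COHORT_SCHEMA_VERSION <- "1.0"

# Canonical on-disk time format: ms with exactly 4 fraction digits, making
# write -> read -> write byte-stable.
format_spike_time <- function(t) sprintf("%.4f", t)

#' Write a cohort to disk
#'
#' Serializes a cohort to a directory holding three text files:
#' `manifest.json` (schema version, seed, group configuration, stimulus
#' catalog, config hash), `sites.csv` (per-site metadata and ground-truth
#' parameters) and `spikes.csv` (one row per spike: `site_id`, `group`,
#' `animal_id`, `depth_um`, `stimulus_id`, `repeat_index`,
#' `spike_time_ms`). Spike times are canonicalized to 4 fraction digits so
#' a write/read/write round trip is byte-identical.
#'
#' @param cohort An `ic_cohort`.
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  grid <- cohort$stimuli$grid
  speech <- cohort$stimuli$speech
  train <- cohort$stimuli$train
  manifest <- list(
    schema_version = COHORT_SCHEMA_VERSION,
    seed = cohort$seed,
    config = lapply(cohort$config, unclass),
    config_hash = config_hash(lapply(cohort$config, unclass)),
    stimuli = list(
      spont = cohort$stimuli$spont,
      grid = if (!is.null(grid)) {
        list(
          frequencies_hz = grid$frequencies,
          intensities_db = grid$intensities,
          duration_ms = grid$stimuli$duration[1],
          ramp_ms = grid$stimuli$ramp[1]
        )
      },
      speech = if (!is.null(speech)) as.data.frame(speech),
      train = if (!is.null(train)) unclass(train)
    ),
    n_burst_repeats = if (!is.null(train)) {
      length(cohort$sites[[1]]$responses$burst_train)
    },
    groups = {
      g <- vapply(cohort$sites, `[[`, character(1), "group")
      as.list(table(factor(g, levels = IC_GROUPS)))
    }
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  write.csv(cohort_sites(cohort), file.path(path, "sites.csv"),
    row.names = FALSE
  )
  rows <- lapply(cohort$sites, function(s) {
    stim_ids <- names(s$responses)
    per_stim <- lapply(stim_ids, function(id) {
      trials <- s$responses[[id]]
      n_spk <- vapply(trials, length, integer(1))
      if (sum(n_spk) == 0) {
        return(NULL)
      }
      data.frame(
        site_id = s$site_id, group = s$group, animal_id = s$animal_id,
        depth_um = s$depth, stimulus_id = id,
        repeat_index = rep.int(seq_along(trials), n_spk),
        spike_time_ms = format_spike_time(unlist(trials, use.names = FALSE)),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per_stim)
  })
  spikes <- do.call(rbind, rows)
  rownames(spikes) <- NULL
  write.csv(spikes, file.path(path, "spikes.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a cohort from disk
#'
#' Inverse of [write_cohort()]. Empty trials are reconstructed from the
#' per-stimulus repeat counts in the manifest, so the round trip is
#' lossless for spike times (at the 4-digit canonicalization), metadata
#' and configuration.
#'
#' @param path Directory written by [write_cohort()].
#' @return An `ic_cohort`.
#' @export
read_cohort <- function(path) {
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (!identical(manifest$schema_version, COHORT_SCHEMA_VERSION)) {
    stop(sprintf(
      "cohort schema version mismatch: file has %s, this package reads %s",
      manifest$schema_version, COHORT_SCHEMA_VERSION
    ))
  }
  grid <- NULL
  if (!is.null(manifest$stimuli$grid)) {
    g <- manifest$stimuli$grid
    f <- g$frequencies_hz
    i <- g$intensities_db
    grid <- build_tone_grid(
      min(f), max(f), log2(max(f) / min(f)) / (length(f) - 1),
      min(i), max(i), if (length(i) > 1) diff(i[1:2]) else 1,
      duration = g$duration_ms, ramp = g$ramp_ms
    )
  }
  speech <- NULL
  if (!is.null(manifest$stimuli$speech)) {
    speech <- as.data.frame(manifest$stimuli$speech)
    class(speech) <- c("speech_catalog", "data.frame")
  }
  train <- NULL
  if (!is.null(manifest$stimuli$train)) {
    tr <- manifest$stimuli$train
    train <- build_noise_train(tr$rate, tr$n_bursts, tr$burst_duration)
  }
  config <- lapply(manifest$config, function(cfg) {
    structure(cfg, class = "group_effects")
  })
  sites_df <- read.csv(file.path(path, "sites.csv"), stringsAsFactors = FALSE)
  spikes_file <- file.path(path, "spikes.csv")
  spikes <- read.csv(spikes_file, stringsAsFactors = FALSE, colClasses = c(
    site_id = "character", group = "character", animal_id = "character",
    depth_um = "numeric", stimulus_id = "character",
    repeat_index = "integer", spike_time_ms = "character"
  ))
  spikes$spike_time_ms <- as.numeric(spikes$spike_time_ms)
  if (anyNA(spikes$spike_time_ms)) {
    bad <- which(is.na(spikes$spike_time_ms))[1]
    stop(sprintf(
      "malformed spike row in %s, line %d: unparseable spike time",
      spikes_file, bad + 1L
    ))
  }
  bad <- which(spikes$spike_time_ms < 0)
  if (length(bad)) {
    stop(sprintf(
      "malformed spike row in %s, line %d: negative spike time %.4f",
      spikes_file, bad[1] + 1L, spikes$spike_time_ms[bad[1]]
    ))
  }
  # expected stimulus list and repeat counts
  expected <- list(spont = manifest$stimuli$spont$n_trials)
  if (!is.null(grid)) {
    for (id in grid$stimuli$stimulus_id) expected[[id]] <- 1L
  }
  if (!is.null(speech)) {
    for (k in seq_len(nrow(speech))) {
      expected[[paste0("speech_", speech$label[k])]] <- speech$n_repeats[k]
    }
  }
  if (!is.null(train)) expected$burst_train <- manifest$n_burst_repeats
  spikes_by_site <- split(spikes, factor(spikes$site_id, levels = sites_df$site_id))
  sites <- vector("list", nrow(sites_df))
  names(sites) <- sites_df$site_id
  for (r in seq_len(nrow(sites_df))) {
    meta <- sites_df[r, ]
    responses <- lapply(expected, function(n_rep) {
      replicate(n_rep, numeric(0), simplify = FALSE)
    })
    ss <- spikes_by_site[[meta$site_id]]
    if (!is.null(ss) && nrow(ss)) {
      by_stim <- split(ss, ss$stimulus_id)
      for (id in names(by_stim)) {
        if (is.null(responses[[id]])) {
          stop(
            "spike row references unknown stimulus_id '", id,
            "' for site ", meta$site_id
          )
        }
        chunk <- by_stim[[id]]
        by_rep <- split(chunk$spike_time_ms, chunk$repeat_index)
        for (rep_id in names(by_rep)) {
          responses[[id]][[as.integer(rep_id)]] <- sort(by_rep[[rep_id]])
        }
      }
    }
    sites[[meta$site_id]] <- list(
      site_id = meta$site_id, group = meta$group, animal_id = meta$animal_id,
      depth = meta$depth_um, cf = meta$cf, threshold = meta$threshold,
      bw10 = meta$bw10, bw40 = meta$bw40,
      onset_latency = meta$onset_latency, peak_latency = meta$peak_latency,
      end_of_peak = meta$end_of_peak,
      spontaneous_rate = meta$spontaneous_rate,
      peak_driven_rate = meta$peak_driven_rate,
      token_effects = NULL,
      responses = responses
    )
  }
  structure(
    list(
      sites = sites, config = config, seed = as.integer(manifest$seed),
      stimuli = list(
        grid = grid, speech = speech, train = train,
        spont = manifest$stimuli$spont
      )
    ),
    class = "ic_cohort"
  )
}

#' Hash an analysis or cohort configuration
#'
#' MD5 of the canonical JSON serialization; changes iff any
#' analysis-relevant parameter changes.
#'
#' @param x Any JSON-serializable configuration object.
#' @return Character MD5 hash.
#' @export
config_hash <- function(x) {
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}
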