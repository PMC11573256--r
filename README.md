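# icresponse

Analysis of multiunit extracellular recordings from the inferior colliculus
(IC), the auditory midbrain, for studies comparing experimental groups of
rats — saline controls, prenatal valproic-acid (VPA) exposure, and
VPA-exposed animals treated with vagus nerve stimulation (VNS) paired with
speech or with tones. It is written for auditory electrophysiologists who
record responses to tone grids, speech tokens and periodic noise-burst
trains and need the full chain from spike times to group-level statistics.

The package implements:

* **Stimulus designs** — the 81 × 16 logarithmic tone search grid
  (1–32 kHz in 0.0625-octave steps, 0–75 dB SPL in 5-dB steps; 1,296
  tones), the VNS-paired multi-tone set, 10-Hz noise-burst trains, and the
  11-token speech catalog with its consonant (0–40 ms), vowel (40–340 ms)
  and whole (0–400 ms) analysis windows.
* **Response metrics** — PSTHs with fixed binning conventions, driven
  firing rates (spontaneous-subtracted), and tone response strength
  (spikes per tone in the (0, 32] ms window).
* **Receptive fields** — frequency-response-area construction,
  median-filter + criterion extraction of threshold, CF, BW10/BW40 and
  onset/peak/end-of-peak latencies, and tonotopy summaries.
* **Neural decoding** — leave-one-out nearest-neighbor PSTH-template
  classification of speech-sound pairs: for each held-out single trial the
  response is assigned to the sound whose mean template lies at minimum
  Euclidean distance; accuracy is averaged over the 36 consonant pairs or
  3 vowel pairs.
* **Temporal following** — driven spikes per burst, burst latencies,
  vector strength `VS = |mean resultant of spike phases|` and the Rayleigh
  statistic `2 n VS²` with its conventional significance criterion 13.8.
* **Group statistics** — Kolmogorov–Smirnov normality screening,
  Kruskal–Wallis omnibus and pairwise Mann–Whitney U tests,
  Brown–Forsythe heteroscedastic ANOVA for receptive-field properties,
  and percent-change effect summaries.
* **A synthetic-cohort generator** — inhomogeneous-Poisson spike trains
  with tuned tone responses, onset + sustained speech responses with
  group-dependent gains, and phase-locked burst responses, so the whole
  pipeline runs and is testable with no recorded data.

## Worked example

Generate a four-group synthetic cohort with the packaged default
calibration (scaled down to 40 sites/group here) and run the pipeline:

```r
library(icresponse)

cohort <- generate_cohort(
  default_group_effects(n_sites = c(40, 40, 40, 40)),
  speech = speech_catalog(),
  train  = build_noise_train(10, 6, 25),
  seed   = 1
)
report <- run_full_analysis(cohort)
report
#> IC analysis report: 160 sites, stages: speech, classifier, bursts
#>   vns_tone_vs_vpa: +40.9% (whole-window speech driven rate)
#>   vns_speech_vs_vpa: -5.3% (whole-window speech driven rate)
#>   comparison blocks: speech_driven_whole, speech_driven_consonant,
#>   speech_driven_vowel, classifier_consonant, classifier_vowel, burst

report$comparisons$speech_driven_whole
#> Group comparison: speech driven rate, 0-400 ms (Hz) (nonparametric family)
#>           group  n   median     mean     se
#>          saline 40 113.9773 121.7321 4.4548
#>             vpa 40  81.7898  83.0582 3.1622
#>  vpa_vns_speech 40  76.6364  78.6872 2.7584
#>    vpa_vns_tone 40 115.3125 117.0028 3.6920
#> Omnibus Kruskal-Wallis: statistic = 77.71, df = 3, p = 9.492e-17
#> Pairwise Mann-Whitney U (two-sided):
#>         group_a        group_b      U  p.value
#>          saline            vpa 1441.0 7.13e-10
#>          saline vpa_vns_speech 1470.5 1.14e-10
#>          saline   vpa_vns_tone  826.0 8.06e-01
#>             vpa vpa_vns_speech  908.0 3.01e-01
#>             vpa   vpa_vns_tone  187.0 3.77e-09
#>  vpa_vns_speech   vpa_vns_tone  150.0 4.11e-10
```

The percent changes are the headline contrasts: VNS-tone pairing raises the
whole-window speech driven rate relative to VPA (calibrated at +44%; +40.9%
in this 40-site draw), while VNS-speech pairing lowers it slightly (−5%
calibrated). The comparison block shows the degraded VPA response relative
to saline, its restoration in the VNS-tone group, and the corresponding
pairwise Mann–Whitney tests. Adding `grid = build_tone_grid(1000, 32000,
0.0625, 0, 75, 5)` to `generate_cohort()` also enables the tone-strength
block and the receptive-field property table (Brown–Forsythe family).

Cohorts serialize to a plain-text directory format (`write_cohort()` /
`read_cohort()`: a JSON manifest plus CSV site and spike tables), and
reports can be written to disk with `run_full_analysis(..., out_dir = )`.

See the methods vignette (`vignettes/ic-analysis-methods.Rmd`) for the
models, extraction rules, calibration rationale and known limitations.

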