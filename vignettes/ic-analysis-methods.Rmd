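---
title: "Methods: analyzing inferior colliculus multiunit responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analyzing inferior colliculus multiunit responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(icresponse)
```

## What this package analyzes

`icresponse` implements an analysis pipeline for multiunit extracellular
recordings from the central nucleus of the inferior colliculus (IC), the
auditory midbrain. The experimental design it targets compares four groups
of rats — saline-exposed controls, rats prenatally exposed to valproic acid
(VPA, a model of autism-like auditory processing deficits), and VPA-exposed
rats treated with vagus nerve stimulation (VNS) paired with either a speech
sound or a set of tones. Each recording site contributes responses to three
stimulus families:

* a pure-tone search grid: 81 frequencies from 1 to 32 kHz in 0.0625-octave
  steps crossed with 16 intensities from 0 to 75 dB SPL in 5-dB steps
  (1,296 tones, one presentation each);
* eleven consonant-vowel-consonant speech tokens, 20 repeats each;
* a train of six 25-ms noise bursts at 10 Hz, 20 repeats.

Because recordings of this kind are not generally redistributable, the
package pairs the analysis stages with a synthetic-cohort generator that
emulates the statistical structure those stages assume. Every stage is
therefore testable end to end, and the packaged default calibration encodes
the group contrasts the pipeline is designed to detect.

## Response metrics

All times are milliseconds from stimulus onset; rates are Hz; intensities
dB SPL. PSTH bins and driven-rate windows are half-open `[t, t + bin)`; the
tone response-strength window is right-closed `(0, 32]` so a spike exactly
at onset is excluded. These conventions are fixed so counts are
bit-reproducible.

The driven firing rate over a window is the mean per-trial spike count
divided by the window duration, minus the spontaneous rate. The spontaneous
rate is estimated per site from a block of stimulus-free trials; subtraction
is applied because "driven" activity means activity above background, and
the subtraction cancels in group contrasts whenever background rates do not
differ between groups. Speech responses are summarized over three windows:
the whole token (0–400 ms), the initial consonant (0–40 ms), and the vowel
(40–340 ms, beginning at the nominal consonant offset). The vowel window is
fixed across tokens: the analysis windows, not per-token acoustic
boundaries, are what the downstream classifier consumes.

## Receptive fields

The frequency response area (FRA) is the matrix of spike counts in the
(0, 32] ms window over the tone grid. Extraction of receptive-field
properties follows standard FRA practice, with every constant exposed as an
argument because conventions differ between laboratories:

1. smooth the FRA with a 3×3 running median (replicate-padded at the matrix
   edges — a truncated edge window would be biased toward the response area
   and can pull the threshold one intensity step low);
2. set the response criterion to the expected spontaneous count plus
   `max(1, 0.2 × (smoothed maximum − spontaneous count))`;
3. the threshold is the lowest intensity whose row holds at least two
   adjacent supra-criterion frequencies; the characteristic frequency (CF)
   is the geometric-mean frequency of that run; BW10/BW40 are the octave
   extents of the supra-criterion run 10/40 dB above threshold, marked `NA`
   when that intensity exceeds the grid maximum.

A site with no qualifying intensity is marked unresponsive — a value, not
an error. Latencies (onset, peak, end of peak) come from criterion
crossings of a pooled 1-ms PSTH: onset is the left edge of the first run of
two or more bins exceeding the spontaneous mean plus twice its SD (Poisson
SD unless a pre-stimulus sample is supplied); the peak is the center of the
maximum bin of that first excursion; end of peak is the left edge of the
first bin after the excursion returns below criterion. The pooled-PSTH
estimator is used rather than per-trial first spikes because grid tones are
presented once each; for 20-repeat burst trains the median first-spike
latency is also computed and is the primary onset measure there, matching
the usual definition for that stimulus.

## Speech-pair decoding

Neural discrimination between two speech sounds uses a leave-one-out
nearest-neighbor template classifier. Single trials are reduced to binned
spike-count vectors — forty 1-ms bins over the first 40 ms for consonant
contrasts, a single 300-ms bin over the vowel window for vowel contrasts —
and each held-out trial is assigned to the sound whose template (the mean
count vector of the remaining repeats) lies at minimum Euclidean distance.
Distances are computed on counts rather than rates; with equal bin widths
the orderings coincide.

Both sounds' templates are leave-one-out averages (19 of 20 repeats), with
folds paired by repeat index. An asymmetric variant (`template = "own"`),
in which only the held-out trial's own sound drops a repeat while the
competing template averages all repeats, is available for comparison; note
that under that rule two statistically identical sounds score below chance,
because the competing template contains the held-out trial itself — which
is why the paired rule is the default. Exact distance ties, common in the
single-bin vowel scheme, are broken uniformly at random under a dedicated
tie seed (kept separate from the simulation RNG), or credited 0.5 in the
deterministic `tie_mode = "expected"`. Consonant discrimination averages
accuracy over all 36 pairs of the nine "-ad" tokens; vowel discrimination
over the three pairs of dad/deed/dood. Accuracy is aggregated per site; the
site is the analysis unit throughout.

## Temporal following of burst trains

For the 10-Hz train, the package reports driven spikes per burst (counts in
a per-burst window, default the full 100-ms inter-burst interval, minus the
expected spontaneous count), onset latency (median first spike across
trials), peak latency (first-excursion PSTH peak), and phase locking.
Vector strength is computed over all spikes pooled across repeats within
the train span, with phase referenced to the 100-ms period; pooling
maximizes the spike count entering the Rayleigh statistic `2 n VS²`, whose
conventional significance criterion is 13.8 (corresponding to p ≈ 10⁻³
under uniform phases).

## Group statistics

Metrics are compared across groups with the nonparametric family:
Kolmogorov–Smirnov normality screening per group (against a normal with
estimated mean and SD), a Kruskal–Wallis omnibus test, and all pairwise
two-sided Mann–Whitney U tests — exact for group sizes up to 20 without
ties, normal approximation with tie correction otherwise. Pairwise p values
are uncorrected by default, reproducing the common reporting convention;
Holm correction is available by flag. Receptive-field properties are
compared with a Brown–Forsythe heteroscedastic one-way ANOVA (equal-means
version, with Satterthwaite fractional denominator df), implemented in the
package and validated against its algebraic equivalence to Welch's t-test
for two groups. Effect summaries use signed percent change of group means.

## The synthetic cohort

The generator produces inhomogeneous-Poisson spike trains from parametric
rate profiles (simulated by thinning against the profile's maximum):

* **Site parameters.** CF log-uniform over 1–32 kHz and mapped
  monotonically to depth (800 µm/octave, 150 µm jitter), producing the
  tonotopic gradient expected of the central nucleus (Spearman ρ ≥ 0.9).
  Thresholds are drawn Normal(group mean, 5 dB) and quantized to the 5-dB
  grid step — a threshold between tested intensities is not identifiable
  from grid responses, and nearest-step rounding keeps the group mean
  unbiased. Transient latencies are drawn around 8.2 / 13.4 / 27.1 ms
  (onset / peak / end of peak), spontaneous rates from a gamma with mean
  30 Hz, and peak driven rates lognormal around 1,200 Hz — values chosen
  once as representative of multiunit IC onset responses.
* **Transients.** Driven components are raised-cosine transients: zero at
  the onset latency, one at the peak latency, and back to zero exactly at
  the end-of-peak latency. A classical alpha function was considered but
  never returns exactly to baseline, which would make the end-of-peak
  parameter unrecoverable by construction.
* **Tuning.** The tone response is scaled by a V-shaped surface: zero below
  threshold, a frequency extent widening linearly through BW10 at
  threshold + 10 dB and BW40 at threshold + 40 dB, and an amplitude ramp
  from 0.6 at threshold to 1 at threshold + 40 dB. The jump to 0.6 at
  threshold makes the threshold crisp on a 5-dB grid, as it is in real FRAs.
* **Speech.** A consonant transient plus a sustained vowel plateau (10% of
  the peak rate). The group `speech_gain` is defined as the exact
  whole-window (0–400 ms) driven gain; `consonant_gain` and `vowel_gain`
  redistribute driven spikes between windows under an internal
  normalization that preserves the whole-window integral, so whole-window
  contrasts equal the configured gain ratios exactly in expectation.
  Per-site, per-token lognormal amplitude factors (mean 1) and a small
  consonant latency jitter make the tokens mutually discriminable without
  altering expected group contrasts.
* **Bursts.** One transient per burst onset, scaled by `burst_gain`, with
  additive group latency shifts.

The default calibration sets the VPA speech gain to 0.70 of saline, the
VNS-tone group to 1.44 × VPA, and the VNS-speech group to 0.95 × VPA with
consonant/vowel redistribution (0.85 / 1.25); tone gains are equal across
groups; group mean thresholds are 17.35 / 17.35 / 17.78 / 12.35 dB; the
VNS-tone group has burst gain 1.30 and −1 ms burst latency shifts. Absolute
driven-rate scale is a free parameter — only ratios are calibrated.

Each site runs on an RNG stream derived deterministically from the master
seed and site index, so cohorts regenerate bit-identically and are
reproducible under parallel generation.

**What the generator does not emulate:** spike waveforms and sorting
artifacts, adaptation across the trial sequence, intensity non-monotonicity
and inhibitory sidebands, multi-peaked receptive fields, correlated noise
across sites or within animals, and litter structure. Passing tests
therefore demonstrate that the pipeline recovers the structure it assumes,
not that real IC data satisfy those assumptions.

## Numerical choices and degenerate inputs

* Grid construction requires the frequency span to divide the octave step
  within 10⁻⁶ octaves and errors with the residual otherwise; empty ranges
  are errors.
* Thinning uses the profile's analytic maximum rate when available, else a
  dense grid evaluation with a 5% margin; negative rates are errors.
* Unresponsive sites, zero-spike vector strength, and excursion-free PSTHs
  are `NA`-marked values, not errors; degenerate all-equal group
  comparisons get p = 1 by convention.
* Classifier ties are detected with a relative tolerance of 10⁻⁹ on
  squared distances.

## Worked example

A small cohort (the defaults use the full site counts 453/374/183/146; here
we scale down for speed) through the whole pipeline:

```{r example, eval = FALSE}
cohort <- generate_cohort(
  default_group_effects(n_sites = c(30, 30, 30, 30)),
  grid = build_tone_grid(1000, 32000, 0.0625, 0, 75, 5),
  speech = speech_catalog(),
  train = build_noise_train(10, 6, 25),
  seed = 1
)
report <- run_full_analysis(cohort)
report$percent_change
report$comparisons$speech_driven_whole
```

## Problem sizes used in validation

The packaged validation runs the percent-change recovery at 150 sites per
group over 10 seeds, the receptive-field calibration recovery at 150 saline
sites over 10 seeds, classifier oracle equivalence on 200 randomized small
instances, and the Kruskal–Wallis type-I simulation at 1,500 null
replicates — sizes at which Monte-Carlo error is small relative to the
effects being checked while the suite stays quick to run.

## Known limitations

The pipeline analyzes one rate other than 10 Hz only in the sense that the
train constructor is parametric; repetition-rate transfer functions are out
of scope. Population (multi-site) decoding, multiclass confusion matrices,
and spike-distance metrics are not implemented. The site-level analysis
reproduces the standard design in this literature; it does not model
site-within-animal non-independence, and per-animal aggregation is
descriptive only.
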