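---
title: "Measuring melodic universals in transmitted whistle sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring melodic universals in transmitted whistle sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whistlechain)
```

This vignette documents the models and procedures the package
implements, the parameters that matter, the numerical choices made where
the methodology leaves them open, and what the synthetic generator does
and does not emulate.

## Data model

A *whistle* is a pitch track paired with an intensity track, both
uniformly sampled (500 samples/s by default). Pitch is carried in
semitones, `st = 12·log2(f / f_ref)`; the reference is 100 Hz (the
common phonetics convention, `st_ref_default`). Every downstream measure
uses only pitch *differences*, so the reference affects nothing but
absolute values in reports. Sample `i` covers the half-open interval
`[start + i/rate, start + (i+1)/rate)`. Unvoiced or missing pitch
samples are carried as `NA`. Twelve whistles form a set (one chain ×
generation cell); sets are organised into a chain dataset.

## Segmentation and pitch targets

Sounding segments are maximal runs of intensity strictly above a silence
threshold. The threshold defaults to 10% of the whistle's maximum
intensity: a relative criterion is robust to recording level, which an
absolute one is not. Two post-passes clean up the runs: silent gaps
shorter than `min_gap_s` (default 0.02 s) are closed, and runs shorter
than `min_segment_s` (default 0.05 s) are discarded. Missing-pitch gaps
of up to 5 samples inside a run are linearly interpolated; longer gaps
split the segment, on the view that a long undefined stretch is evidence
of a break rather than a tracking glitch.

Pitch targets are the peaks and valleys of the contour, located at
zero-crossings of the first derivative. Applied verbatim to a 500-Hz
track this rule fires on every wiggle, so two noise-handling parameters
are exposed: a centred moving average of `smooth_window = 5` samples
(10 ms) and a minimum prominence of 0.5 st — an interior target must
differ from both flanking targets by at least that much. Detection is a
hysteresis walk: a reversal is confirmed only once the contour has
retraced ≥ 0.5 st from the running extreme, which guarantees the
alternation of peaks and valleys. Segment endpoints always count as
targets (kinds `start`/`end`): contour classification needs endpoint
heights to tell ascending from horizontal, and the tone-target
distribution uses the same target set for consistency. An
endpoint-exclusive mode (`endpoints = FALSE`) exists for sensitivity
analyses.

## Discrete pitches and scale size

Per set, all target semitone values are pooled. Non-uniformity is
measured by a χ² goodness-of-fit statistic over 1-st bins spanning
`[floor(min), ceiling(max))` of the observed targets; the bin width and
an explicit range override are exposed. Degrees of freedom therefore
vary a little from set to set with the occupied range; that is a
property of the procedure, not a bug.

"Peakiness" is measured with one-dimensional Gaussian mixtures with free
means and free variances, `k = 1..k_max` (default 10), selected by BIC.
A single fit is not stable under random initialisation, so the statistic
is the *average selected k over 100 runs*, each run initialised from a
fresh random subset (50 points) of the data; `mclust` performs the
fitting. The run average — not any single run — feeds the scale-size
check `round(mean k) ≤ 7`.

## Contours

Successive target differences with |Δ| below `slide_threshold` (default
1 st) are treated as level and dropped; the remaining signed moves give
the category: none → horizontal; all up → ascending; all down →
descending; one up→down change → arched; one down→up → u-shaped; two or
more changes → undulating. The 1-st default mirrors the prominence scale
of target detection; because the choice is a judgement call, it is a
first-class parameter and classification is invariant to pitch
transposition by construction.

## Intervals and the compression ratio

A segment's onset is its first pitch sample. Onset-to-onset interval
magnitudes are per-observation measures. The compression ratio of a
whistle is `mean(shuffled) / mean(actual)`: the mean absolute onset
difference under 100 seeded uniform-random permutations of segment
order, over the actual mean. Whistles with fewer than two segments, or a
zero actual mean, yield an explicit undefined marker rather than a
value. The 750-cent (7.5 st) reference for "small" intervals and the
9-s phrase bound are reporting constants, not filters.

## Building blocks, entropy, chunk strength

Segment similarity is Derivative Dynamic Time Warping: each segment's
pitch sequence is smoothed (same 5-sample window), linearly resampled to
`resample_len = 50` points, converted to Keogh–Pazzani local derivative
estimates `d_i = ((q_i − q_{i−1}) + (q_{i+1} − q_{i−1})/2)/2`, and
aligned by dynamic programming with squared derivative differences as
local cost. The reported distance is the square root of the accumulated
cost divided by the warping-path length — an RMS derivative difference
in semitones per resample step. This normalisation is a deliberate
choice: a bare accumulated cost is meaningless next to a fixed merge
threshold, and the RMS form puts same-shape renderings (different
duration, offset, mild jitter: distances ≲ 0.03) and different contour
shapes (≳ 0.1) on opposite sides of the default threshold 0.08. The
threshold is nonetheless calibration-dependent and exposed as a
first-class parameter. Derivatives make the distance offset-invariant;
resampling makes it duration-invariant; no pitch centring is applied
because the derivative transform already removes offsets.

Blocks are formed by average-linkage agglomerative clustering, merging
while some pair of clusters has linkage distance strictly below the
threshold ("no pair closer than the threshold remains"). The cut is
implemented by merge count on the `hclust` tree so that a merge at
exactly the threshold is *not* taken and threshold 0 leaves every
segment its own block.

Block use is summarised by Shannon entropy over relative block
frequencies, in bits (base 2 — the natural reporting unit for a
"number of effective categories" reading; the base is a parameter).
Associative chunk strength enumerates every bigram and trigram token
within each whistle's block sequence (tokens never cross whistle
boundaries), counts type frequencies across the set, and averages the
type frequency over all tokens. Bigrams and trigrams are pooled into a
single token list before averaging, reading "the average of the bigram
and trigram frequencies" as one average; a split variant
(mean of the two per-order averages) is available via `pooled = FALSE`.

## Trends

Each measure is fitted as `value ~ generation + (1 | chain)` by REML,
with Satterthwaite-approximated t-tests (`lmerTest`) — the standard
toolchain for this design. Set-level measures contribute one row per
(chain, generation); whistle- and segment-level measures (intervals,
compression ratio, phrase measures, targets per segment) are fitted at
the observation level rather than pre-averaged. Shuffled-vs-actual
interval comparisons use `value ~ generation * dataset + (1 | chain)`.
Contour proportions are fitted per type on the per-set proportions with
no transformation. A single-chain table degrades to ordinary least
squares with an explicit `ols_fallback` flag; a zero-variance measure
returns a flagged degenerate fit with slope 0. Singular random-effect
fits (common when chain differences are small) are flagged, not hidden.

## The synthetic generator

The generator is the package's acceptance surface: it renders exactly
the kind of data the measures consume, with known structure planted.

* **Study conditions.** Defaults follow the experimental design the
  package targets: 4 chains × 10 generations × 12 whistles, 500
  samples/s, pitch confined to 450–2500 Hz (the slide-whistle range),
  mean segment duration 0.5 s, ~4 segments and ~0.15-s gaps per whistle
  giving a mean whistle duration near 2.5 s. Durations are
  gamma-distributed (shape 4) around their means: always positive,
  mildly skewed, a standard choice for duration data.
* **Planted structure.** A set draws `n_pitch_levels` equally spaced
  scale levels (spacing 5 st) centred in the range, and `n_block_types`
  segment templates, each a contour label (drawn from `contour_mixture`)
  anchored on the scale. Whistles are sequences of templates drawn with
  weight `exp(−concentration · (j−1))`, so `block_reuse_concentration`
  tunes label entropy from uniform to single-block. `n_pitch_levels`
  semantics: 0 renders fully continuous contours (anchors via a random
  walk whose mean absolute step is `onset_interval_scale_st`); 1 pins
  anchors to one level but keeps excursion sizes continuous; ≥ 2 snaps
  every target to the scale. This keeps non-horizontal contours
  renderable at low discreteness while making the mixture component
  count rise as levels are added.
* **Noise.** Targets are jittered per rendering (`level_jitter_sd`,
  default 0.5 st — motor imprecision on a slide whistle) and samples
  perturbed by `pitch_noise_sd` (default 0.05 st; pitch tracks of
  strongly tonal whistle sounds are nearly noise-free). With both set to
  0, segmentation recovers the planted boundaries exactly, contour
  classification reproduces the planted labels, and block clustering
  reproduces the planted partition — the measurement-consistency
  property the tests assert.
* **Drift.** A chain plan linearly interpolates every numeric parameter
  across generations (integer fields rounded, the contour mixture
  renormalised). Linear drift makes slope recovery by the linear trend
  models well-posed. Per-(chain, generation) seeds are derived from one
  master seed by a small deterministic hash, so any cell is reproducible
  in isolation.
* **What it does not emulate.** No audio, no formant or breath
  artefacts, no mechanistic model of human memory or production error —
  drift stands in for the aggregate effect of transmission. Passing
  recovery tests therefore demonstrates that the *measurement machinery*
  is correct and directionally sensitive, not that real chains behave
  this way.

## Problem sizes and numerical choices

The validation suite runs planted-recovery checks at deliberately modest
sizes chosen to estimate each property well: 200 random sequence pairs
against a brute-force DDTW oracle (tolerance 1e-9, predecessor ties
broken diagonal-first in both implementations); 50 planted two-family
clustering instances; exact permutation enumeration for compression
ratios up to 5 segments with the Monte-Carlo estimate required within 3
standard errors; 100 mixture runs per planted component count 1–5 at
6-st separation and 0.3-st jitter; 100 simulated 4 × 10 datasets for
slope recovery (planted −0.09, chain SD 0.3, residual SD 0.2) plus 500
null datasets for the type-I error of the generation test; and one full
drifting chain at study scale for directional end-to-end recovery. Ties
in `hclust` are resolved by its deterministic merge order; all
stochastic steps take explicit seeds.

## Known limitations

* The DDTW merge threshold is meaningful only relative to the package's
  own normalisation; comparing its value against other implementations
  requires re-calibration.
* Mixture-count averaging inherits BIC's occasional overfit on single
  runs; only the run average is a stable statistic.
* Contour proportions are modelled untransformed, so fitted values are
  not constrained to [0, 1]; with ~10 generations per chain this is the
  conventional, interpretable choice.
* The generator's drift is linear and noise Gaussian; real transmission
  chains need not be either. Directional recovery under these
  conditions is a necessary, not sufficient, check for field data.
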