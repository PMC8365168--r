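# whistlechain

Measurement machinery for detecting **melodic statistical universals** in
sets of whistled signals produced in iterated-learning transmission
chains, together with a synthetic chain generator that plants known
structure so every measure can be validated by parameter recovery.

## The problem

In transmission-chain (iterated learning) experiments, one participant's
reproductions of a set of signals become the next participant's learning
input. Weak individual biases get amplified over generations, and
continuous signal systems — e.g. melodies produced on a slide whistle —
can be tested for the gradual emergence of the statistical universals of
melody: discrete pitches, scales of few (≤ 7) elements, descending or
arched contours, small melodic intervals, motivic patterns, repetition,
and short (≤ 9 s) phrases.

The raw material is a set of whistles per (chain, generation), each
whistle a pitch track (semitones, `st = 12·log2(f/f_ref)`) paired with an
intensity track, uniformly sampled at 500 samples/s. This package covers
everything downstream of pitch extraction:

1. **Segmentation** — whistles are split into sounding segments at silent
   breaks in the intensity track; each segment is annotated with *pitch
   targets*: the peaks and valleys at zero-crossings of the (smoothed)
   pitch derivative, plus the segment endpoints.
2. **Discrete pitches / few elements** — per-set tone-target
   distributions are tested against uniformity (χ² = Σ(O−E)²/E) and
   modelled with 1-D Gaussian mixtures; the number of components is
   selected by BIC per run, averaged over 100 randomly initialised runs,
   and checked against the ≤ 7-elements rule.
3. **Contours** — each segment is classified as horizontal / ascending /
   descending / arched / u-shaped / undulating from the signed sequence
   of its target-to-target slides.
4. **Intervals** — onset-to-onset intervals of consecutive segments, and
   the *interval compression ratio*: mean |interval| under random segment
   reshuffling divided by the actual mean |interval| (> 1 means real
   orderings use smaller jumps than chance).
5. **Motifs and repetition** — segments are clustered into building
   blocks with average-linkage agglomerative clustering on Derivative
   Dynamic Time Warping (DDTW) distances, merging while any pair of
   clusters is closer than a threshold (default 0.08). Block use is
   summarised by Shannon entropy `H = −Σ pᵢ log₂ pᵢ` and by associative
   chunk strength (the mean set-wide frequency of the bigram/trigram
   tokens occurring in the whistles' block sequences).
6. **Phrases** — segments per whistle and whistle durations.
7. **Trends** — every measure is modelled as
   `value ~ generation + (1 | chain)` by REML (lmerTest), with
   Satterthwaite degrees of freedom, reported in the `b ± SEM, P` form.

Because real transmission-chain recordings are rarely redistributable,
the package ships a first-class synthetic generator
(`generate_whistle_set()`, `generate_chain_dataset()`) that renders pitch
and intensity tracks from a planted grammar — a discrete pitch scale,
contour-typed block templates, tunable block reuse, and linear
per-generation parameter drift — and returns the full ground truth.

## Worked example

```r
library(whistlechain)

p <- generator_params(n_pitch_levels = 3, n_block_types = 3,
                      block_reuse_concentration = 1, seed = 7)
out <- generate_whistle_set(p, chain_id = "chain1", generation = 1)
out$set
#> <whistle_set> chain chain1 gen 1: 12 whistles

tg <- collect_tone_targets(out$set)            # 127 tone targets
chi2_uniform(tg)[c("chi2", "df")]
#> $chi2 [1] 205.1654
#> $df   [1] 12
gmm_component_count(tg, n_runs = 25, seed = 1)
#> <discreteness> mean components 3.04 over 25 runs (n = 127 targets)

mm <- motif_measures(out$set)
c(blocks = mm$n_blocks, entropy = mm$entropy, chunk = mm$chunk_strength)
#> blocks 3.000  entropy 0.989  chunk 6.97
attr(out$ground_truth, "planted_entropy")
#> [1] 1.055
```

The set was planted with a 3-level scale and 3 building blocks: the
mixture recovers ~3 components, clustering recovers 3 blocks, and the
measured block entropy (0.99 bits) sits close to the planted label
entropy (1.06 bits). A drifting chain recovers trends:

```r
start <- generator_params(n_pitch_levels = 1, block_reuse_concentration = 0.2)
end   <- generator_params(n_pitch_levels = 4, block_reuse_concentration = 2.5)
plan  <- chain_plan(start, end, n_generations = 10, n_chains = 4)
res   <- generate_chain_dataset(plan, seed = 7)
tab   <- measure_chain_dataset(res$dataset, mu = mu_control(gmm_runs = 25),
                               seed = 7)
fit_generation_trend(tab, "entropy")
#> <trend_fit> entropy ~ generation [lmm_satterthwaite]
#>   b = -0.1678 +/- 0.01708 SEM, df = 35.00, t = -9.819, P = 1.363e-11
fit_generation_trend(tab, "mean_components")
#> <trend_fit> mean_components ~ generation [lmm_satterthwaite]
#>   b = 0.2059 +/- 0.03927 SEM, df = 38.00, t = 5.243, P = 6.2e-06
```

Entropy falls and the component count rises across generations — the
planted directions, recovered with the same machinery one would apply to
real chains.

A YAML-driven pipeline (`pipeline_simulate()`, `pipeline_measure()`,
`pipeline_trends()`, or `inst/cli/whistlechain.R` from a shell) chains
the stages with one master seed; reruns are byte-identical.

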