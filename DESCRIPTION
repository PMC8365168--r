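Package: whistlechain
Title: Melodic Statistical Universals in Transmitted Whistle Signal Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measurement pipeline for detecting melodic statistical
    universals in sets of whistled signals produced in iterated-learning
    transmission chains. Whistles arrive as paired pitch (semitone) and
    intensity tracks sampled at 500 samples per second; the package
    segments them into sounding parts, annotates pitch targets at
    derivative zero-crossings, and computes per-set measures of pitch
    discreteness (chi-square non-uniformity and Gaussian-mixture
    component counts), scale size, melodic contour type proportions,
    onset-to-onset interval sizes and shuffle-null interval compression
    ratios, building-block structure via Derivative Dynamic Time Warping
    and average-linkage clustering (Shannon entropy, associative chunk
    strength), and phrase measures. Per-measure generation trends are
    fitted with linear mixed-effects models (random intercept per chain,
    Satterthwaite tests). A synthetic transmission-chain generator with
    planted, known structure supports end-to-end validation by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    lmerTest,
    mclust,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
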