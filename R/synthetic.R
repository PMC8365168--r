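## Synthetic whistle-chain generator with planted, known structure.
##
## A whistle set is rendered from a small grammar: a discrete pitch scale
## (n_pitch_levels equally spaced levels), a pool of segment templates
## ("building blocks", each a contour label anchored on scale levels), and
## per-whistle block sequences drawn with a tunable reuse concentration.
## Pitch tracks are piecewise-linear contours through the template targets
## plus Gaussian jitter and sample noise; intensity is a constant positive
## plateau during segments and 0 in gaps. Everything planted (segment
## boundaries, block ids, contour labels, target values, label entropy) is
## returned as ground truth so every measure can be verified by recovery.
##
## Discreteness semantics: n_pitch_levels = 0 renders fully continuous
## contours (anchor heights and excursion amplitudes redrawn per
## rendering); 1 pins anchors to a single level but keeps excursions
## continuous; >= 2 snaps all targets to the scale.

#' Generator parameters for one whistle set
#'
#' @param n_whistles Whistles per set (default 12).
#' @param pitch_floor_hz,pitch_ceiling_hz Instrument range (defaults 450 and
#'   2500 Hz); all rendered pitch stays inside it.
#' @param sample_rate Samples per second (default 500).
#' @param n_pitch_levels Number of discrete scale levels (0 = continuous).
#' @param level_spacing_st Spacing between adjacent scale levels (default 5
#'   semitones).
#' @param level_jitter_sd Per-rendering Gaussian jitter of target values
#'   around their levels (semitones, default 0.5 — slide-whistle motor
#'   imprecision).
#' @param n_block_types Number of segment templates (default 4).
#' @param block_reuse_concentration >= 0; template j is drawn with weight
#'   proportional to `exp(-concentration * (j - 1))`, so 0 is uniform use
#'   (maximal label entropy) and large values concentrate use on one block.
#' @param distinct_block_contours Give templates pairwise distinct contour
#'   labels when `n_block_types <= 6` (default TRUE), which keeps planted
#'   blocks separable by DDTW.
#' @param contour_mixture Named probabilities over the six contour labels.
#' @param mean_segment_duration_s Mean sounding-segment duration (default
#'   0.5 s).
#' @param mean_gap_duration_s Mean silent-gap duration (default 0.15 s).
#' @param segments_per_whistle_mean Mean segments per whistle (default 4;
#'   1 + Poisson).
#' @param onset_interval_scale_st Mean absolute onset-to-onset step of the
#'   anchor random walk in continuous mode (`n_pitch_levels <= 1`; default
#'   3 semitones). With a discrete scale, onsets are the templates' anchor
#'   levels instead.
#' @param pitch_noise_sd Per-sample pitch track noise (default 0.05 st;
#'   pitch tracks of whistled tones are nearly noise-free).
#' @param intensity_level Plateau intensity during segments (default 70).
#' @param seed Optional integer seed.
#' @return List of class `generator_params`.
#' @export
generator_params <- function(n_whistles = 12, pitch_floor_hz = 450,
                             pitch_ceiling_hz = 2500, sample_rate = 500,
                             n_pitch_levels = 3, level_spacing_st = 5,
                             level_jitter_sd = 0.5, n_block_types = 4,
                             block_reuse_concentration = 1,
                             distinct_block_contours = TRUE,
                             contour_mixture = c(horizontal = 0.25,
                                                 ascending = 0.15,
                                                 descending = 0.25,
                                                 arched = 0.10,
                                                 u_shaped = 0.10,
                                                 undulating = 0.15),
                             mean_segment_duration_s = 0.5,
                             mean_gap_duration_s = 0.15,
                             segments_per_whistle_mean = 4,
                             onset_interval_scale_st = 3,
                             pitch_noise_sd = 0.05,
                             intensity_level = 70, seed = NULL) {
  p <- as.list(environment())
  class(p) <- "generator_params"
  validate_generator_params(p)
  p
}

validate_generator_params <- function(p) {
  stopifnot(p$n_whistles >= 1, p$sample_rate > 0,
            p$pitch_floor_hz > 0, p$pitch_ceiling_hz > p$pitch_floor_hz,
            p$n_pitch_levels >= 0, p$level_spacing_st > 0,
            p$level_jitter_sd >= 0, p$n_block_types >= 1,
            p$block_reuse_concentration >= 0,
            p$mean_segment_duration_s > 0, p$mean_gap_duration_s > 0,
            p$segments_per_whistle_mean >= 1,
            p$onset_interval_scale_st > 0, p$pitch_noise_sd >= 0,
            p$intensity_level > 0)
  if (!identical(sort(names(p$contour_mixture)), sort(contour_levels)))
    stop("contour_mixture must be named over the six contour labels")
  if (abs(sum(p$contour_mixture) - 1) > 1e-8)
    stop("contour_mixture must sum to 1")
  if (any(p$contour_mixture < 0)) stop("contour_mixture must be nonnegative")
  if (p$n_pitch_levels >= 2 &&
      p$level_spacing_st < 3 * p$level_jitter_sd)
    stop("infeasible params: level_spacing_st < 3 * level_jitter_sd ",
         "(levels not separable)")
  span <- max(p$n_pitch_levels - 1, 0) * p$level_spacing_st
  range_st <- hz_to_semitones(p$pitch_ceiling_hz) -
    hz_to_semitones(p$pitch_floor_hz)
  if (span + 6 * p$level_jitter_sd > range_st)
    stop("infeasible params: scale span exceeds the instrument range")
  invisible(p)
}

## target-height offsets per contour label, in units of one "excursion":
## the planted targets of each template, before anchoring
contour_offsets <- function(label) {
  switch(label,
         horizontal = c(0, 0),
         ascending = c(0, 1),
         descending = c(0, -1),
         arched = c(0, 1, 0),
         u_shaped = c(0, -1, 0),
         undulating = c(0, 1, 0, 1),
         stop("unknown contour label: ", label))
}

make_block_templates <- function(p, levels_st) {
  nb <- p$n_block_types
  mix <- p$contour_mixture[contour_levels]
  pool <- contour_levels[mix > 0]
  if (p$distinct_block_contours && nb <= length(pool)) {
    labels <- sample(pool, nb, replace = FALSE, prob = mix[pool])
  } else if (p$distinct_block_contours && nb <= 6) {
    # not enough supported labels to keep them distinct: reuse the pool
    labels <- c(pool, sample(pool, nb - length(pool), replace = TRUE,
                             prob = mix[pool]))
  } else {
    labels <- sample(contour_levels, nb, replace = TRUE, prob = mix)
  }
  k <- p$n_pitch_levels
  lapply(seq_len(nb), function(j) {
    lab <- labels[j]
    off <- contour_offsets(lab)
    if (k >= 2) {
      steps <- if (k > 2) sample(1:(k - 1), 1) else 1L
      lv_off <- off * steps
      lo <- 1L - min(lv_off); hi <- k - max(lv_off)
      anchor <- if (hi > lo) sample(lo:hi, 1) else lo
      list(label = lab, discrete = TRUE,
           level_indices = anchor + lv_off, anchor_index = anchor)
    } else {
      list(label = lab, discrete = FALSE, offsets = off)
    }
  })
}

render_segment <- function(tmpl, p, anchor_st, levels_st, n_samp) {
  if (tmpl$discrete) {
    heights <- levels_st[tmpl$level_indices] +
      rnorm(length(tmpl$level_indices), 0, p$level_jitter_sd)
  } else {
    amp <- runif(1, 4.5, 7)
    heights <- anchor_st + tmpl$offsets * amp +
      rnorm(length(tmpl$offsets), 0, p$level_jitter_sd)
  }
  pos <- round(seq(1, n_samp, length.out = length(heights)))
  contour <- approx(pos, heights, xout = seq_len(n_samp))$y
  contour <- contour + rnorm(n_samp, 0, p$pitch_noise_sd)
  list(pitch = pmin(pmax(contour, hz_to_semitones(p$pitch_floor_hz)),
                    hz_to_semitones(p$pitch_ceiling_hz)),
       targets = heights, label = tmpl$label)
}

#' Generate one synthetic whistle set with ground truth
#'
#' @param params A [generator_params()].
#' @param chain_id,generation Identifiers stamped on the whistles.
#' @return List with elements `set` (a [whistle_set()]) and `ground_truth`
#'   (data.frame, one row per planted segment: whistle_id, segment_index,
#'   block, contour, onset_st, n_targets, start_sample, end_sample), with
#'   attributes `planted_entropy` (bits, from the realised block labels)
#'   and `levels_st` (the planted scale).
#' @export
generate_whistle_set <- function(params, chain_id = "chain1",
                                 generation = 1L) {
  validate_generator_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  rate <- params$sample_rate
  floor_st <- hz_to_semitones(params$pitch_floor_hz)
  ceil_st <- hz_to_semitones(params$pitch_ceiling_hz)
  centre <- (floor_st + ceil_st) / 2
  k <- params$n_pitch_levels
  levels_st <- if (k >= 1)
    centre + params$level_spacing_st * (seq_len(k) - (k + 1) / 2)
  else numeric(0)
  band <- c(max(floor_st + 8.5, centre - 7), min(ceil_st - 8.5, centre + 7))

  templates <- make_block_templates(params, levels_st)
  wts <- exp(-params$block_reuse_concentration *
               (seq_len(params$n_block_types) - 1))

  whistles <- list(); gt <- list()
  for (wi in seq_len(params$n_whistles)) {
    wid <- sprintf("w%02d", wi)
    n_seg <- 1L + rpois(1, max(params$segments_per_whistle_mean - 1, 0))
    blocks <- sample.int(params$n_block_types, n_seg, replace = TRUE,
                         prob = wts)
    anchor <- runif(1, band[1], band[2])  # continuous-mode onset walk
    pitch <- numeric(0); intens <- numeric(0)
    lead <- round(0.05 * rate)
    pitch <- rep(NA_real_, lead); intens <- rep(0, lead)
    for (si in seq_len(n_seg)) {
      if (si > 1L) {
        gap <- max(rgamma(1, shape = 4,
                          scale = params$mean_gap_duration_s / 4), 0.04)
        ng <- round(gap * rate)
        pitch <- c(pitch, rep(NA_real_, ng)); intens <- c(intens, rep(0, ng))
        step <- rexp(1, rate = 1 / params$onset_interval_scale_st)
        dir <- sample(c(-1, 1), 1)
        if (anchor + dir * step > band[2] || anchor + dir * step < band[1])
          dir <- -dir
        anchor <- min(max(anchor + dir * step, band[1]), band[2])
      }
      dur <- max(rgamma(1, shape = 4,
                        scale = params$mean_segment_duration_s / 4), 0.12)
      n_samp <- round(dur * rate)
      rs <- render_segment(templates[[blocks[si]]], params, anchor,
                           levels_st, n_samp)
      start_sample <- length(pitch) + 1L
      pitch <- c(pitch, rs$pitch)
      intens <- c(intens, rep(params$intensity_level, n_samp))
      gt[[length(gt) + 1L]] <- data.frame(
        chain_id = chain_id, generation = as.integer(generation),
        whistle_id = wid, segment_index = si, block = blocks[si],
        contour = rs$label, onset_st = rs$targets[1],
        n_targets = length(rs$targets),
        start_sample = start_sample,
        end_sample = start_sample + n_samp, stringsAsFactors = FALSE)
    }
    tail <- round(0.05 * rate)
    pitch <- c(pitch, rep(NA_real_, tail)); intens <- c(intens, rep(0, tail))
    whistles[[wi]] <- whistle(wid, chain_id, generation,
                              pitch_track(pitch, rate),
                              intensity_track(intens, rate))
  }
  gt <- do.call(rbind, gt)
  attr(gt, "planted_entropy") <- shannon_entropy(gt$block)
  attr(gt, "levels_st") <- levels_st
  list(set = whistle_set(whistles), ground_truth = gt)
}

#' Transmission-chain plan: linear drift between two parameter settings
#'
#' Generation g of `n_generations` uses parameters linearly interpolated
#' between `start_params` (g = 1) and `end_params` (g = n_generations);
#' integer-valued fields are rounded, the contour mixture is renormalised
#' after interpolation. Non-numeric fields must agree between start and
#' end.
#'
#' @param start_params,end_params [generator_params()] objects.
#' @param n_generations Generations per chain (default 10).
#' @param n_chains Number of parallel chains (default 4).
#' @return List of class `chain_plan`.
#' @export
chain_plan <- function(start_params, end_params = start_params,
                       n_generations = 10, n_chains = 4) {
  stopifnot(inherits(start_params, "generator_params"),
            inherits(end_params, "generator_params"),
            n_generations >= 2, n_chains >= 1)
  for (f in c("distinct_block_contours")) {
    if (!identical(start_params[[f]], end_params[[f]]))
      stop("start and end params may differ only in numeric fields: ", f)
  }
  structure(list(start_params = start_params, end_params = end_params,
                 n_generations = as.integer(n_generations),
                 n_chains = as.integer(n_chains)),
            class = "chain_plan")
}

interp_params <- function(plan, g) {
  t <- (g - 1) / (plan$n_generations - 1)
  a <- plan$start_params; b <- plan$end_params
  p <- a
  num <- c("n_whistles", "pitch_floor_hz", "pitch_ceiling_hz", "sample_rate",
           "n_pitch_levels", "level_spacing_st", "level_jitter_sd",
           "n_block_types", "block_reuse_concentration",
           "mean_segment_duration_s", "mean_gap_duration_s",
           "segments_per_whistle_mean", "onset_interval_scale_st",
           "pitch_noise_sd", "intensity_level")
  for (f in num) p[[f]] <- (1 - t) * a[[f]] + t * b[[f]]
  for (f in c("n_whistles", "n_pitch_levels", "n_block_types"))
    p[[f]] <- as.integer(round(p[[f]]))
  mix <- (1 - t) * a$contour_mixture[contour_levels] +
    t * b$contour_mixture[contour_levels]
  p$contour_mixture <- mix / sum(mix)
  p
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Deterministic integer hash of the master seed and a tag (e.g. stage name
#' plus chain/generation), kept below 2^31.
#'
#' @param master Integer master seed.
#' @param ... Further integer or character tags.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  h <- as.numeric(master) %% 2147483647
  for (x in list(...)) {
    xs <- if (is.character(x)) sum(utf8ToInt(x) * seq_along(utf8ToInt(x)))
          else as.numeric(x)
    h <- (h * 69069 + xs * 101 + 7) %% 2147483647
  }
  as.integer(h) + 1L
}

#' Generate a full synthetic transmission-chain dataset
#'
#' @param plan A [chain_plan()].
#' @param seed Master seed; each (chain, generation) set gets an
#'   independent seed derived from it.
#' @return List with `dataset` (a [chain_dataset()]), `ground_truth`
#'   (row-bound per-segment records), and `planted` (data.frame per set:
#'   chain_id, generation, planted_entropy, n_pitch_levels, n_block_types).
#' @export
generate_chain_dataset <- function(plan, seed = 1L) {
  stopifnot(inherits(plan, "chain_plan"))
  sets <- list(); gts <- list(); planted <- list()
  for (ci in seq_len(plan$n_chains)) {
    cid <- sprintf("chain%d", ci)
    for (g in seq_len(plan$n_generations)) {
      p <- interp_params(plan, g)
      p$seed <- derive_seed(seed, "set", ci, g)
      out <- generate_whistle_set(p, chain_id = cid, generation = g)
      sets[[length(sets) + 1L]] <- out$set
      gts[[length(gts) + 1L]] <- out$ground_truth
      planted[[length(planted) + 1L]] <- data.frame(
        chain_id = cid, generation = g,
        planted_entropy = attr(out$ground_truth, "planted_entropy"),
        n_pitch_levels = p$n_pitch_levels,
        n_block_types = p$n_block_types, stringsAsFactors = FALSE)
    }
  }
  list(dataset = chain_dataset(sets), ground_truth = do.call(rbind, gts),
       planted = do.call(rbind, planted))
}

#' Parameter preset emulating a deliberately unstructured initial set
#'
#' Continuous pitch (no scale), no block reuse, descending-heavy contour
#' mixture — the analogue of a hand-designed seed set that avoids obvious
#' reuse of basic elements.
#'
#' @param ... Overrides passed to [generator_params()].
#' @export
initial_set_params <- function(...) {
  generator_params(n_pitch_levels = 0, n_block_types = 6,
                   block_reuse_concentration = 0,
                   distinct_block_contours = TRUE,
                   contour_mixture = c(horizontal = 0.18, ascending = 0.14,
                                       descending = 0.32, arched = 0.0,
                                       u_shaped = 0.12, undulating = 0.24),
                   ...)
}
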