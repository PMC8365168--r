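## Per-set measures for the pitch-domain universals:
## MU1 discrete pitches (chi-square non-uniformity of tone targets +
##     Gaussian-mixture component counts averaged over random restarts),
## MU2 few (<= 7) scale elements, MU3 contour type proportions,
## MU4 onset-to-onset intervals and the shuffle-null compression ratio,
## MU7 phrase measures (segments per whistle, whistle duration).

#' Collect tone-target semitone values for a whistle set
#'
#' Concatenates the values of all pitch targets (start, peaks, valleys, end)
#' over all segments of all whistles, in whistle/segment/target order.
#'
#' @param set A [whistle_set()].
#' @param control A [seg_control()].
#' @param endpoints Include the segment endpoints as targets (default TRUE);
#'   `FALSE` restricts to interior extrema.
#' @return Numeric vector of semitone values (possibly empty).
#' @export
collect_tone_targets <- function(set, control = seg_control(),
                                 endpoints = TRUE) {
  tab <- segment_table(set, control)
  if (!endpoints) tab <- tab[tab$kind %in% c("peak", "valley"), , drop = FALSE]
  tab$target_st
}

#' Chi-square goodness-of-fit against a uniform target distribution
#'
#' Targets are binned into consecutive `bin_width`-semitone bins covering
#' `[floor(min), ceiling(max))` (or an explicit `range` override) and the
#' counts are tested against equal expected counts.
#'
#' @param targets Numeric semitone values.
#' @param bin_width Bin width in semitones (default 1).
#' @param range Optional length-2 numeric overriding the binning range.
#' @return List with `chi2`, `df`, `p_value`, `n_targets`, `n_bins` and
#'   logical `degenerate` (TRUE when all targets fall in a single bin).
#' @export
chi2_uniform <- function(targets, bin_width = 1, range = NULL) {
  targets <- targets[is.finite(targets)]
  if (length(targets) < 2L) stop("need at least 2 targets")
  if (is.null(range)) range <- c(floor(min(targets)), ceiling(max(targets)))
  breaks <- seq(range[1], range[2] + bin_width - 1e-9, by = bin_width)
  if (breaks[length(breaks)] < range[2]) breaks <- c(breaks, range[2])
  k <- length(breaks) - 1L
  if (k < 2L)
    return(list(chi2 = 0, df = 0L, p_value = NA_real_,
                n_targets = length(targets), n_bins = k, degenerate = TRUE))
  ## half-open [a, b) bins; the last bin closed so the max is counted
  bin <- findInterval(targets, breaks, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), k)
  counts <- tabulate(bin, nbins = k)
  ht <- suppressWarnings(stats::chisq.test(counts))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, n_targets = length(targets), n_bins = k,
       degenerate = FALSE)
}

#' Gaussian-mixture component count for tone targets
#'
#' Fits one-dimensional Gaussian mixtures with free means and variances for
#' k = 1..`k_max`, selecting k by BIC, once per run. Each run uses a fresh
#' random-subset initialisation, so repeated runs can select different
#' models; the per-run counts and their mean are returned (the discreteness
#' statistic is the mean over runs).
#'
#' @param targets Numeric semitone values (at least `k_max + 1`).
#' @param k_max Largest number of components considered (default 10).
#' @param n_runs Number of runs to average (default 100).
#' @param seed Optional integer seed making the run sequence reproducible.
#' @param subset_size Size of the random initialisation subset (default 50).
#' @return List of class `discreteness_result`: `mean_components`,
#'   `per_run_components`, `n_targets`, `k_max`.
#' @export
gmm_component_count <- function(targets, k_max = 10, n_runs = 100,
                                seed = NULL, subset_size = 50) {
  targets <- targets[is.finite(targets)]
  n <- length(targets)
  stopifnot(k_max >= 1, n_runs >= 1)
  if (n < k_max + 1L) {
    warning("fewer targets than k_max + 1; lowering k_max to ", n - 1L)
    k_max <- n - 1L
  }
  if (k_max < 1L) stop("need at least 2 targets")
  if (!is.null(seed)) set.seed(seed)
  per_run <- integer(n_runs)
  for (r in seq_len(n_runs)) {
    sub <- sample.int(n, min(n, subset_size))
    fit <- suppressWarnings(
      mclust::Mclust(targets, G = seq_len(k_max), modelNames = "V",
                     initialization = list(subset = sub), verbose = FALSE))
    if (is.null(fit))  # rare init failure: fall back to equal-variance family
      fit <- suppressWarnings(
        mclust::Mclust(targets, G = seq_len(k_max), verbose = FALSE))
    per_run[r] <- fit$G
  }
  structure(list(mean_components = mean(per_run), per_run_components = per_run,
                 n_targets = n, k_max = k_max),
            class = "discreteness_result")
}

#' @export
print.discreteness_result <- function(x, ...) {
  cat(sprintf("<discreteness> mean components %.2f over %d runs (n = %d targets)\n",
              x$mean_components, length(x$per_run_components), x$n_targets))
  invisible(x)
}

#' Few-elements (scale size) check
#'
#' Musical scales typically use few (<= 7) elements per octave; the check
#' passes when the rounded mean component count does not exceed `limit`.
#'
#' @param result A `discreteness_result` from [gmm_component_count()], or a
#'   bare numeric mean.
#' @param limit Element limit (default 7).
#' @return List with `pass` (logical) and `count` (rounded mean).
#' @export
few_elements_check <- function(result, limit = 7) {
  m <- if (inherits(result, "discreteness_result")) result$mean_components
       else as.numeric(result)
  count <- round(m)
  list(pass = count <= limit, count = count)
}

contour_levels <- c("horizontal", "ascending", "descending",
                    "arched", "u_shaped", "undulating")

#' Classify a segment's melodic contour
#'
#' Successive target differences smaller in magnitude than `slide_threshold`
#' are treated as level and dropped; the remaining signed moves decide the
#' category: none left = horizontal; all up = ascending; all down =
#' descending; one up-to-down change = arched; one down-to-up = u-shaped;
#' two or more changes = undulating.
#'
#' @param targets Numeric target values (semitones), or a `targets`
#'   data.frame from [detect_targets()].
#' @param slide_threshold Minimum semitone move to count as a slide
#'   (default 1).
#' @return A single character label; a degenerate (single-target) input is
#'   `"horizontal"` with attribute `degenerate = TRUE`.
#' @export
classify_contour <- function(targets, slide_threshold = 1) {
  v <- if (is.data.frame(targets)) targets$value else as.numeric(targets)
  if (length(v) < 2L)
    return(structure("horizontal", degenerate = TRUE))
  d <- diff(v)
  d <- d[abs(d) >= slide_threshold]
  if (!length(d)) return("horizontal")
  s <- sign(d)
  changes <- sum(diff(s) != 0)
  if (changes == 0) {
    if (s[1] > 0) "ascending" else "descending"
  } else if (changes == 1) {
    if (s[1] > 0) "arched" else "u_shaped"
  } else "undulating"
}

#' Contour-type proportions for a whistle set
#'
#' @param set A [whistle_set()].
#' @param control A [seg_control()].
#' @param slide_threshold Passed to [classify_contour()].
#' @return Named numeric over the six contour labels, summing to 1.
#' @export
contour_proportions <- function(set, control = seg_control(),
                                slide_threshold = 1) {
  stopifnot(inherits(set, "whistle_set"))
  labs <- unlist(lapply(set$whistles, function(w) {
    vapply(annotate_whistle(w, control), function(s)
      classify_contour(s$targets, slide_threshold), character(1))
  }))
  if (!length(labs)) stop("whistle set has no segments")
  tab <- table(factor(labs, levels = contour_levels))
  p <- as.numeric(tab) / length(labs)
  names(p) <- contour_levels
  p
}

segment_onsets <- function(w, control = seg_control()) {
  vapply(segment_whistle(w, control), function(s) s$pitch_values[1], numeric(1))
}

#' Onset-to-onset interval magnitudes for a whistle
#'
#' A segment's onset is its first pitch sample (semitones). Returns
#' `|onset[i+1] - onset[i]|` for consecutive segments; empty when the
#' whistle has fewer than 2 segments.
#'
#' @param w A [whistle()], or a numeric vector of onsets.
#' @param control A [seg_control()].
#' @return Numeric vector of nonnegative semitone magnitudes.
#' @export
onset_intervals <- function(w, control = seg_control()) {
  onsets <- if (inherits(w, "whistle")) segment_onsets(w, control)
            else as.numeric(w)
  if (length(onsets) < 2L) return(numeric(0))
  abs(diff(onsets))
}

#' Interval compression ratio of a whistle
#'
#' Compares the actual mean absolute onset-to-onset interval to its
#' expectation under random reordering of the segments: `n_shuffles`
#' uniform-random permutations of segment order are drawn, the mean
#' absolute onset difference of each is computed, and the ratio
#' mean(shuffled) / mean(actual) is returned. Values above 1 mean the real
#' ordering uses smaller pitch jumps than chance.
#'
#' @param w A [whistle()], or a numeric vector of segment onsets.
#' @param n_shuffles Number of random permutations (default 100).
#' @param seed Optional integer seed.
#' @param control A [seg_control()].
#' @return List with `actual_intervals`, `mean_actual`, `mean_shuffled`,
#'   `compression_ratio` and logical `defined`. With fewer than 2 segments
#'   or zero actual mean the result is an undefined marker
#'   (`defined = FALSE`, ratio `NA`).
#' @export
compression_ratio <- function(w, n_shuffles = 100, seed = NULL,
                              control = seg_control()) {
  onsets <- if (inherits(w, "whistle")) segment_onsets(w, control)
            else as.numeric(w)
  actual <- if (length(onsets) >= 2L) abs(diff(onsets)) else numeric(0)
  mean_actual <- if (length(actual)) mean(actual) else NA_real_
  if (length(onsets) < 2L || !isTRUE(mean_actual > 0))
    return(list(actual_intervals = actual, mean_actual = mean_actual,
                mean_shuffled = NA_real_, compression_ratio = NA_real_,
                defined = FALSE))
  if (!is.null(seed)) set.seed(seed)
  sh <- vapply(seq_len(n_shuffles), function(i)
    mean(abs(diff(onsets[sample.int(length(onsets))]))), numeric(1))
  list(actual_intervals = actual, mean_actual = mean_actual,
       mean_shuffled = mean(sh),
       compression_ratio = mean(sh) / mean_actual, defined = TRUE)
}

#' Phrase measures for a whistle
#'
#' @param w A [whistle()].
#' @param control A [seg_control()].
#' @return List with `n_segments`, `whistle_duration_s` (end of last segment
#'   minus start of first), `mean_segment_duration_s`, and logical
#'   `defined` (FALSE when the whistle has no segments).
#' @export
phrase_measures <- function(w, control = seg_control()) {
  segs <- segment_whistle(w, control)
  if (!length(segs))
    return(list(n_segments = 0L, whistle_duration_s = 0,
                mean_segment_duration_s = 0, defined = FALSE))
  rate <- segs[[1]]$rate
  dur <- (segs[[length(segs)]]$end_sample - segs[[1]]$start_sample) / rate
  list(n_segments = length(segs), whistle_duration_s = dur,
       mean_segment_duration_s = mean(vapply(segs, `[[`, numeric(1), "duration")),
       defined = TRUE)
}
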