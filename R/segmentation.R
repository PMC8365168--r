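## Segmentation of whistles into sounding parts using the intensity track,
## and annotation of each part with pitch targets (peaks/valleys at
## zero-crossings of the smoothed pitch derivative, plus the endpoints).

#' Segmentation and target-detection parameters
#'
#' @param silence_threshold Absolute intensity threshold; samples strictly
#'   above it count as sounding. `NULL` (default) uses
#'   `silence_frac * max(intensity)` per whistle, which is robust to
#'   recording level.
#' @param silence_frac Fraction of the whistle's maximum intensity used when
#'   `silence_threshold` is `NULL` (default 0.1).
#' @param min_gap_s Silent gaps shorter than this are closed (default 0.02 s).
#' @param min_segment_s Sounding runs shorter than this are discarded
#'   (default 0.05 s).
#' @param max_na_gap Missing-pitch gaps of at most this many samples inside a
#'   sounding run are linearly interpolated; longer gaps split the segment
#'   (default 5).
#' @param smooth_window Centred moving-average window (samples) applied to
#'   pitch before derivative zero-crossing detection (default 5 = 10 ms at
#'   500/s).
#' @param min_prominence_st Interior extrema must differ from both flanking
#'   targets by at least this many semitones (default 0.5).
#' @return A list of class `seg_control`.
#' @export
seg_control <- function(silence_threshold = NULL, silence_frac = 0.1,
                        min_gap_s = 0.02, min_segment_s = 0.05,
                        max_na_gap = 5, smooth_window = 5,
                        min_prominence_st = 0.5) {
  stopifnot(silence_frac >= 0, min_gap_s >= 0, min_segment_s >= 0,
            max_na_gap >= 0, smooth_window >= 1, min_prominence_st >= 0)
  structure(list(silence_threshold = silence_threshold,
                 silence_frac = silence_frac, min_gap_s = min_gap_s,
                 min_segment_s = min_segment_s, max_na_gap = max_na_gap,
                 smooth_window = as.integer(smooth_window),
                 min_prominence_st = min_prominence_st),
            class = "seg_control")
}

## runs of TRUE as (start, end] half-open sample index pairs (1-based start)
bool_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values] + 0L)
}

interp_short_na <- function(v, max_gap) {
  if (!anyNA(v)) return(v)
  idx <- which(!is.na(v))
  if (length(idx) < 2L) return(v)
  runs <- bool_runs(is.na(v))
  if (is.null(dim(runs)) || nrow(runs) == 0L) return(v)
  for (k in seq_len(nrow(runs))) {
    a <- runs[k, 1]; b <- runs[k, 2]
    if (b - a + 1L <= max_gap && a > 1L && b < length(v)) {
      v[a:b] <- approx(c(a - 1L, b + 1L), c(v[a - 1L], v[b + 1L]),
                       xout = a:b)$y
    }
  }
  v
}

#' Split a whistle into sounding segments
#'
#' Segments are maximal runs of samples with intensity strictly above the
#' silence threshold, after (a) closing silent gaps shorter than `min_gap_s`
#' and (b) discarding runs shorter than `min_segment_s`. Missing-pitch gaps
#' of at most `max_na_gap` samples inside a run are interpolated; longer
#' gaps split the run.
#'
#' @param w A [whistle()].
#' @param control A [seg_control()].
#' @return List of `segment` objects (possibly empty), each with fields
#'   `whistle_id`, `index`, `start_sample`/`end_sample` (half-open, 1-based
#'   start), `pitch_values` (semitones), `duration` (s) and `rate`.
#' @export
segment_whistle <- function(w, control = seg_control()) {
  stopifnot(inherits(w, "whistle"), inherits(control, "seg_control"))
  ii <- w$intensity$values
  thr <- control$silence_threshold
  if (is.null(thr)) thr <- control$silence_frac * max(ii)
  sounding <- ii > thr
  if (!any(sounding)) return(list())
  rate <- w$pitch$sample_rate
  min_gap <- floor(control$min_gap_s * rate)
  min_seg <- ceiling(control$min_segment_s * rate)

  ## close short silent gaps (interior only)
  if (min_gap > 0) {
    gaps <- bool_runs(!sounding)
    for (k in seq_len(nrow(gaps))) {
      a <- gaps[k, 1]; b <- gaps[k, 2]
      if (a > 1L && b < length(sounding) && (b - a + 1L) < min_gap)
        sounding[a:b] <- TRUE
    }
  }
  runs <- bool_runs(sounding)
  keep <- (runs[, 2] - runs[, 1] + 1L) >= max(min_seg, 2L)
  runs <- runs[keep, , drop = FALSE]

  ## split runs at long missing-pitch gaps
  pieces <- list()
  for (k in seq_len(nrow(runs))) {
    a <- unname(runs[k, 1]); b <- unname(runs[k, 2])
    pv <- interp_short_na(w$pitch$values[a:b], control$max_na_gap)
    if (!anyNA(pv)) {
      pieces[[length(pieces) + 1L]] <- list(a = a, b = b, pv = pv)
    } else {
      ok <- bool_runs(!is.na(pv))
      for (j in seq_len(nrow(ok))) {
        if (ok[j, 2] - ok[j, 1] + 1L >= max(min_seg, 2L))
          pieces[[length(pieces) + 1L]] <-
            list(a = a + ok[j, 1] - 1L, b = a + ok[j, 2] - 1L,
                 pv = pv[ok[j, 1]:ok[j, 2]])
      }
    }
  }
  lapply(seq_along(pieces), function(i) {
    p <- pieces[[i]]
    structure(list(whistle_id = w$whistle_id, index = i,
                   start_sample = p$a, end_sample = p$b + 1L,
                   pitch_values = p$pv,
                   duration = (p$b + 1L - p$a) / rate, rate = rate),
              class = "segment")
  })
}

#' @export
print.segment <- function(x, ...) {
  cat(sprintf("<segment %s/%d> samples [%d,%d), %.3f s\n",
              x$whistle_id, x$index, x$start_sample, x$end_sample, x$duration))
  invisible(x)
}

moving_average <- function(v, window) {
  window <- min(window, length(v))
  if (window <= 1L) return(v)
  half <- (window - 1L) %/% 2L
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (window - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect pitch targets in a segment
#'
#' The pitch contour is smoothed with a centred moving average, then interior
#' targets are direction reversals (zero-crossings of the first difference)
#' whose extremum differs from both flanking targets by at least
#' `min_prominence_st`, found with a hysteresis walk. The segment endpoints
#' are always included as targets of kind `start` and `end`; interior kinds
#' alternate `peak`/`valley`.
#'
#' @param seg A `segment` from [segment_whistle()], or a numeric pitch vector.
#' @param control A [seg_control()] (fields `smooth_window`,
#'   `min_prominence_st`).
#' @return A data.frame with columns `sample_index` (within segment),
#'   `value` (semitones, smoothed) and `kind`.
#' @export
detect_targets <- function(seg, control = seg_control()) {
  v <- if (inherits(seg, "segment")) seg$pitch_values else as.numeric(seg)
  if (length(v) < 2L) stop("target detection needs at least 2 pitch samples")
  sm <- moving_average(v, control$smooth_window)
  p <- control$min_prominence_st
  n <- length(sm)

  idx <- integer(0); val <- numeric(0); kind <- character(0)
  emit <- function(i, k) {
    idx[length(idx) + 1L] <<- i
    val[length(val) + 1L] <<- sm[i]
    kind[length(kind) + 1L] <<- k
  }
  ## hysteresis walk: a reversal is confirmed once the contour moves back by
  ## >= p from the running extreme, so every emitted interior target has
  ## prominence >= p against both flanking targets
  dir <- 0L; runmin <- 1L; runmax <- 1L; cand <- 1L
  for (i in 2:n) {
    if (dir == 0L) {
      if (sm[i] >= sm[runmax]) runmax <- i
      if (sm[i] <= sm[runmin]) runmin <- i
      if (sm[i] - sm[runmin] >= p) {
        if (runmin > 1L && sm[1] - sm[runmin] >= p) emit(runmin, "valley")
        dir <- 1L; cand <- i
      } else if (sm[runmax] - sm[i] >= p) {
        if (runmax > 1L && sm[runmax] - sm[1] >= p) emit(runmax, "peak")
        dir <- -1L; cand <- i
      }
    } else if (dir == 1L) {
      if (sm[i] > sm[cand]) cand <- i
      else if (sm[cand] - sm[i] >= p) { emit(cand, "peak"); dir <- -1L; cand <- i }
    } else {
      if (sm[i] < sm[cand]) cand <- i
      else if (sm[i] - sm[cand] >= p) { emit(cand, "valley"); dir <- 1L; cand <- i }
    }
  }
  ## first/last interior target must also clear the endpoint value by p
  while (length(idx) && abs(val[1] - sm[1]) < p) {
    idx <- idx[-1]; val <- val[-1]; kind <- kind[-1]
  }
  while (length(idx) && abs(val[length(val)] - sm[n]) < p) {
    k <- length(idx); idx <- idx[-k]; val <- val[-k]; kind <- kind[-k]
  }
  data.frame(sample_index = c(1L, idx, n),
             value = c(sm[1], val, sm[n]),
             kind = c("start", kind, "end"),
             stringsAsFactors = FALSE)
}

#' Segment a whistle and annotate targets
#'
#' Convenience wrapper: [segment_whistle()] then [detect_targets()] per
#' segment (attached as element `targets`).
#'
#' @inheritParams segment_whistle
#' @return List of segments, each with a `targets` data.frame.
#' @export
annotate_whistle <- function(w, control = seg_control()) {
  segs <- segment_whistle(w, control)
  lapply(segs, function(s) {
    s$targets <- detect_targets(s, control)
    s
  })
}

#' Tidy table of segments and targets for a whistle set
#'
#' @param set A [whistle_set()].
#' @param control A [seg_control()].
#' @return data.frame with one row per target: `whistle_id, segment_index,
#'   start_s, end_s, target_index, target_s, target_st, kind`.
#' @export
segment_table <- function(set, control = seg_control()) {
  stopifnot(inherits(set, "whistle_set"))
  rows <- list()
  for (w in set$whistles) {
    t0 <- w$pitch$start_time
    for (s in annotate_whistle(w, control)) {
      tg <- s$targets
      rows[[length(rows) + 1L]] <- data.frame(
        whistle_id = w$whistle_id, segment_index = s$index,
        start_s = t0 + (s$start_sample - 1L) / s$rate,
        end_s = t0 + (s$end_sample - 1L) / s$rate,
        target_index = seq_len(nrow(tg)),
        target_s = t0 + (s$start_sample - 1L + tg$sample_index - 1L) / s$rate,
        target_st = tg$value, kind = tg$kind, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(whistle_id = character(), segment_index = integer(),
                      start_s = numeric(), end_s = numeric(),
                      target_index = integer(), target_s = numeric(),
                      target_st = numeric(), kind = character()))
  do.call(rbind, rows)
}
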