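## MU5/MU6: building-block discovery and sequential structure.
##
## Segment similarity is Derivative Dynamic Time Warping (DDTW): sequences
## are resampled to a common length, converted to local derivative
## estimates, and aligned by DTW with squared derivative differences as
## local cost. The reported distance is the RMS derivative difference along
## the optimal warping path (square root of accumulated cost over path
## length), in semitones per resample step — invariant to pitch offset and,
## through resampling, to duration. Blocks are average-linkage clusters of
## segments, merged while any pair of clusters is closer than a stopping
## threshold (0.08 by default).

resample_linear <- function(x, len) {
  if (length(x) == len) return(as.numeric(x))
  approx(seq_along(x), x, xout = seq(1, length(x), length.out = len))$y
}

#' Keogh-Pazzani local derivative estimate
#'
#' `d[i] = ((q[i] - q[i-1]) + (q[i+1] - q[i-1]) / 2) / 2` for interior
#' points; the boundary points copy their neighbour's estimate.
#'
#' @param q Numeric sequence (length >= 3).
#' @return Numeric vector of the same length.
#' @export
kp_derivative <- function(q) {
  n <- length(q)
  if (n < 3L) stop("derivative estimate needs at least 3 samples")
  d <- numeric(n)
  i <- 2:(n - 1)
  d[i] <- ((q[i] - q[i - 1]) + (q[i + 1] - q[i - 1]) / 2) / 2
  d[1] <- d[2]; d[n] <- d[n - 1]
  d
}

#' Derivative Dynamic Time Warping distance between two pitch sequences
#'
#' @param a,b Numeric pitch sequences in semitones (length >= 3).
#' @param resample_len Common length both sequences are linearly resampled
#'   to before the derivative transform (default 50).
#' @return Nonnegative distance; 0 for identical sequences and for
#'   sequences differing only by a constant offset.
#' @export
ddtw_distance <- function(a, b, resample_len = 50) {
  if (length(a) < 3L || length(b) < 3L)
    stop("ddtw_distance needs sequences of at least 3 samples")
  stopifnot(resample_len >= 3)
  da <- kp_derivative(resample_linear(a, resample_len))
  db <- kp_derivative(resample_linear(b, resample_len))
  res <- dtw_core(da, db)
  sqrt(res[1] / res[2])
}

#' Pairwise DDTW distance matrix for a list of segments
#'
#' @param segments List of `segment` objects (or bare numeric pitch
#'   vectors).
#' @param resample_len Passed to [ddtw_distance()].
#' @param smooth_window Centred moving-average window applied to each
#'   sequence first (default 5; 1 disables).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
ddtw_distance_matrix <- function(segments, resample_len = 50,
                                 smooth_window = 5) {
  seqs <- lapply(segments, function(s) {
    v <- if (inherits(s, "segment")) s$pitch_values else as.numeric(s)
    moving_average(v, smooth_window)
  })
  n <- length(seqs)
  ## derivative once per segment, DP per pair
  ders <- lapply(seqs, function(v)
    kp_derivative(resample_linear(v, resample_len)))
  D <- matrix(0, n, n)
  if (n > 1L) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    res <- dtw_core(ders[[i]], ders[[j]])
    D[i, j] <- D[j, i] <- sqrt(res[1] / res[2])
  }
  D
}

#' Cluster segments into building blocks
#'
#' Average-linkage agglomerative clustering on the pairwise DDTW matrix.
#' Merging continues while some pair of clusters has average-linkage
#' distance strictly below `threshold` and stops as soon as none is left,
#' reproducing a "no pair of segments closer than the threshold" stopping
#' rule. `threshold = 0` therefore leaves every segment its own block.
#'
#' @param segments List of `segment` objects or numeric pitch vectors.
#' @param threshold Stopping distance (default 0.08).
#' @param resample_len,smooth_window Passed to [ddtw_distance_matrix()].
#' @param dist_matrix Optional precomputed distance matrix (skips DDTW).
#' @return List of class `block_labeling`: `segment_keys` (data.frame
#'   whistle_id/segment_index when available), `labels` (integer block ids,
#'   numbered by first appearance), `n_blocks`, `block_frequencies`.
#' @export
cluster_building_blocks <- function(segments, threshold = 0.08,
                                    resample_len = 50, smooth_window = 5,
                                    dist_matrix = NULL) {
  n <- length(segments)
  if (n == 0L) stop("no segments to cluster")
  keys <- if (all(vapply(segments, inherits, logical(1), "segment")))
    data.frame(whistle_id = vapply(segments, `[[`, character(1), "whistle_id"),
               segment_index = vapply(segments, `[[`, numeric(1), "index"))
  else data.frame(whistle_id = NA_character_, segment_index = seq_len(n))
  if (n == 1L) {
    labels <- 1L
  } else {
    D <- if (is.null(dist_matrix))
      ddtw_distance_matrix(segments, resample_len, smooth_window)
    else as.matrix(dist_matrix)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    k <- n - sum(hc$height < threshold)  # strict <: merge only below threshold
    raw <- stats::cutree(hc, k = k)
    labels <- match(raw, unique(raw))    # renumber by first appearance
  }
  freq <- tabulate(labels)
  structure(list(segment_keys = keys, labels = labels,
                 n_blocks = max(labels),
                 block_frequencies = freq),
            class = "block_labeling")
}

#' @export
print.block_labeling <- function(x, ...) {
  cat(sprintf("<block_labeling> %d segments in %d blocks\n",
              length(x$labels), x$n_blocks))
  invisible(x)
}

#' Shannon entropy of building-block use
#'
#' `H = -sum(p_i * log(p_i))` over the blocks' relative frequencies; log
#' base 2 (bits) by default.
#'
#' @param labeling A `block_labeling`, or a vector of block labels (one
#'   entry per segment; frequencies are tabulated).
#' @param base Logarithm base (default 2).
#' @return Entropy (0 for a single block, `log(k, base)` for k equiprobable
#'   blocks).
#' @export
shannon_entropy <- function(labeling, base = 2) {
  counts <- if (inherits(labeling, "block_labeling")) labeling$block_frequencies
            else as.numeric(table(labeling))
  entropy_from_counts(counts, base)
}

#' Entropy from explicit block counts
#' @param counts Numeric vector of block occurrence counts.
#' @param base Logarithm base (default 2).
#' @export
entropy_from_counts <- function(counts, base = 2) {
  counts <- counts[counts > 0]
  p <- counts / sum(counts)
  -sum(p * log(p, base = base))
}

#' Per-whistle block label sequences from a labeling
#'
#' @param labeling A `block_labeling` whose `segment_keys` carry whistle
#'   ids.
#' @return Named list of integer label vectors, one per whistle, in segment
#'   order.
#' @export
block_sequences <- function(labeling) {
  stopifnot(inherits(labeling, "block_labeling"))
  sp <- split(seq_along(labeling$labels), labeling$segment_keys$whistle_id)
  lapply(sp, function(ii)
    labeling$labels[ii[order(labeling$segment_keys$segment_index[ii])]])
}

#' Associative chunk strength of a whistle set
#'
#' Every bigram and trigram token inside each whistle's block-label sequence
#' is enumerated (tokens never cross whistle boundaries), type frequencies
#' are counted across the whole set, and the mean over all tokens of their
#' type's frequency is returned. By default bigrams and trigrams are pooled
#' into one token list before averaging; `pooled = FALSE` averages the
#' bigram mean and the trigram mean instead.
#'
#' @param sequences List of per-whistle label vectors (see
#'   [block_sequences()]), or a `block_labeling`.
#' @param pooled Pool bigram and trigram tokens before averaging (default
#'   TRUE).
#' @return List with `chunk_strength`, `n_tokens`, `defined` (FALSE when no
#'   whistle has at least 2 blocks).
#' @export
chunk_strength <- function(sequences, pooled = TRUE) {
  if (inherits(sequences, "block_labeling"))
    sequences <- block_sequences(sequences)
  ngrams <- function(x, k) {
    if (length(x) < k) return(character(0))
    vapply(seq_len(length(x) - k + 1L),
           function(i) paste(x[i:(i + k - 1L)], collapse = "-"),
           character(1))
  }
  bi <- unlist(lapply(sequences, ngrams, 2L))
  tri <- unlist(lapply(sequences, ngrams, 3L))
  if (!length(bi))
    return(list(chunk_strength = NA_real_, n_tokens = 0L, defined = FALSE))
  if (pooled) {
    tokens <- c(bi, tri)
    freq <- table(tokens)
    cs <- mean(as.numeric(freq[tokens]))
  } else {
    fb <- table(bi); ft <- table(tri)
    mb <- mean(as.numeric(fb[bi]))
    mt <- if (length(tri)) mean(as.numeric(ft[tri])) else NA_real_
    cs <- mean(c(mb, mt), na.rm = TRUE)
  }
  list(chunk_strength = cs, n_tokens = length(bi) + length(tri),
       defined = TRUE)
}

#' Motif measures for a whistle set
#'
#' Segments the set, clusters segments into building blocks by DDTW, and
#' computes Shannon entropy and associative chunk strength.
#'
#' @param set A [whistle_set()].
#' @param control A [seg_control()].
#' @param threshold,resample_len,smooth_window Passed to
#'   [cluster_building_blocks()].
#' @param base Entropy log base.
#' @return List with `labeling`, `entropy`, `chunk_strength`, `n_blocks`,
#'   `n_segments`.
#' @export
motif_measures <- function(set, control = seg_control(), threshold = 0.08,
                           resample_len = 50, smooth_window = 5, base = 2) {
  stopifnot(inherits(set, "whistle_set"))
  segs <- unlist(lapply(set$whistles, annotate_whistle, control = control),
                 recursive = FALSE)
  if (!length(segs)) stop("whistle set has no segments")
  lab <- cluster_building_blocks(segs, threshold, resample_len, smooth_window)
  cs <- chunk_strength(lab)
  list(labeling = lab, entropy = shannon_entropy(lab, base),
       chunk_strength = cs$chunk_strength, n_blocks = lab$n_blocks,
       n_segments = length(segs))
}
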