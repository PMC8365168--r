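# Fixtures are built in code: whistles assembled from explicit pitch pieces
# with silent gaps, and prototype contour shapes for the classifier and
# clustering tests.

# Build a whistle from a list of pitch pieces (semitone vectors); gaps of
# `gap` samples (NA pitch, zero intensity) separate the pieces.
make_whistle <- function(pieces, gap = 100L, rate = 500, level = 70,
                         whistle_id = "w1", chain_id = "c1",
                         generation = 1L, lead = 0L) {
  pitch <- rep(NA_real_, lead); intens <- rep(0, lead)
  for (i in seq_along(pieces)) {
    if (i > 1L) {
      pitch <- c(pitch, rep(NA_real_, gap)); intens <- c(intens, rep(0, gap))
    }
    pitch <- c(pitch, pieces[[i]])
    intens <- c(intens, rep(level, length(pieces[[i]])))
  }
  whistle(whistle_id, chain_id, generation,
          pitch_track(pitch, rate), intensity_track(intens, rate))
}

make_set <- function(whistle_pieces, ...) {
  ws <- lapply(seq_along(whistle_pieces), function(i)
    make_whistle(whistle_pieces[[i]], whistle_id = sprintf("w%02d", i), ...))
  whistle_set(ws)
}

# Piecewise-linear contour through target heights, n samples.
contour_piece <- function(heights, n = 150) {
  pos <- round(seq(1, n, length.out = length(heights)))
  stats::approx(pos, heights, xout = seq_len(n))$y
}

# Two shape families whose derivative patterns differ an order of magnitude
# beyond the clustering threshold: fast large oscillation vs near-flat.
# Family members vary in overall pitch offset (and, for the flat family,
# duration), which DDTW is invariant to.
planted_families <- function(n_per = 5) {
  osc <- replicate(n_per, {
    contour_piece(60 + runif(1, -3, 3) + c(0, 12, 0, 12, 0, 12, 0), n = 150)
  }, simplify = FALSE)
  flat <- replicate(n_per, {
    contour_piece(rep(50 + runif(1, -3, 3), 2), n = sample(140:170, 1))
  }, simplify = FALSE)
  c(osc, flat)
}

# Prototype shapes for the six contour categories.
proto_contour <- function(label, base = 60, amp = 6, n = 150) {
  h <- switch(label,
              horizontal = c(base, base),
              ascending = c(base, base + amp),
              descending = c(base, base - amp),
              arched = c(base, base + amp, base),
              u_shaped = c(base, base - amp, base),
              undulating = c(base, base + amp, base, base + amp))
  contour_piece(h, n)
}
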