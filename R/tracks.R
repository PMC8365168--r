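## Containers for pitch/intensity tracks, whistles, sets and chains.
##
## Pitch is stored in semitones (st = 12 * log2(f / f_ref), reference
## 100 Hz by convention); intensity in arbitrary nonnegative units with
## 0 meaning silence. Tracks are uniformly sampled; sample i covers the
## half-open interval [start_time + i/rate, start_time + (i+1)/rate).

#' Default semitone reference frequency (Hz)
#'
#' Only pitch differences matter for every measure in the package, so this
#' choice affects nothing except where absolute target values sit in reports.
#' 100 Hz is the common phonetics convention.
#' @export
st_ref_default <- 100

#' Convert frequency in Hz to semitones
#'
#' `st = 12 * log2(freq_hz / ref_hz)`. Strictly increasing in `freq_hz`;
#' adding an octave adds exactly 12 semitones.
#'
#' @param freq_hz Positive frequency (Hz). Vectorised.
#' @param ref_hz Positive reference frequency (Hz).
#' @return Semitone value(s) relative to `ref_hz`.
#' @examples
#' hz_to_semitones(200, 100)  # one octave = 12
#' @export
hz_to_semitones <- function(freq_hz, ref_hz = st_ref_default) {
  if (any(!is.finite(freq_hz)) || any(freq_hz <= 0))
    stop("freq_hz must be positive and finite")
  if (length(ref_hz) != 1L || !is.finite(ref_hz) || ref_hz <= 0)
    stop("ref_hz must be a single positive frequency")
  12 * log2(freq_hz / ref_hz)
}

#' Convert semitones back to Hz
#' @param st Semitone value(s).
#' @param ref_hz Positive reference frequency (Hz).
#' @export
semitones_to_hz <- function(st, ref_hz = st_ref_default) {
  if (length(ref_hz) != 1L || !is.finite(ref_hz) || ref_hz <= 0)
    stop("ref_hz must be a single positive frequency")
  ref_hz * 2^(st / 12)
}

new_track <- function(values, sample_rate, start_time, type) {
  if (length(values) < 1L) stop("a track needs at least one sample")
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be positive")
  if (type == "pitch") {
    if (any(!is.finite(values) & !is.na(values)))
      stop("pitch values must be finite or NA (unvoiced)")
  } else {
    if (any(is.na(values)) || any(values < 0))
      stop("intensity values must be nonnegative and present")
  }
  structure(
    list(values = as.numeric(values),
         sample_rate = as.numeric(sample_rate),
         start_time = as.numeric(start_time)),
    class = c(paste0(type, "_track"), "wc_track"))
}

#' Pitch track constructor
#'
#' @param values Pitch samples in semitones; `NA` marks unvoiced/missing
#'   samples.
#' @param sample_rate Samples per second (default 500).
#' @param start_time Time of the first sample (seconds).
#' @return An object of class `pitch_track`.
#' @export
pitch_track <- function(values, sample_rate = 500, start_time = 0)
  new_track(values, sample_rate, start_time, "pitch")

#' Intensity track constructor
#'
#' @param values Nonnegative intensity samples; 0 means silence.
#' @inheritParams pitch_track
#' @return An object of class `intensity_track`.
#' @export
intensity_track <- function(values, sample_rate = 500, start_time = 0)
  new_track(values, sample_rate, start_time, "intensity")

#' @export
print.wc_track <- function(x, ...) {
  cat(sprintf("<%s> %d samples @ %g/s, start %.3f s\n",
              class(x)[1], length(x$values), x$sample_rate, x$start_time))
  invisible(x)
}

#' @export
length.wc_track <- function(x) length(x$values)

track_times <- function(track)
  track$start_time + (seq_along(track$values) - 1) / track$sample_rate

#' Whistle: one signal with paired pitch and intensity tracks
#'
#' @param whistle_id Identifier, unique within its set.
#' @param chain_id Transmission-chain identifier.
#' @param generation Generation number (integer >= 0).
#' @param pitch A [pitch_track()].
#' @param intensity An [intensity_track()] with the same length and rate.
#' @return An object of class `whistle`.
#' @export
whistle <- function(whistle_id, chain_id, generation, pitch, intensity) {
  stopifnot(inherits(pitch, "pitch_track"), inherits(intensity, "intensity_track"))
  if (length(pitch$values) != length(intensity$values) ||
      pitch$sample_rate != intensity$sample_rate)
    stop("pitch and intensity tracks must have equal sample counts and rates")
  if (generation < 0 || generation != round(generation))
    stop("generation must be a nonnegative integer")
  structure(list(whistle_id = as.character(whistle_id),
                 chain_id = as.character(chain_id),
                 generation = as.integer(generation),
                 pitch = pitch, intensity = intensity),
            class = "whistle")
}

#' @export
print.whistle <- function(x, ...) {
  cat(sprintf("<whistle %s> chain %s gen %d, %d samples (%.2f s)\n",
              x$whistle_id, x$chain_id, x$generation, length(x$pitch$values),
              length(x$pitch$values) / x$pitch$sample_rate))
  invisible(x)
}

#' One generation's set of whistles
#'
#' @param whistles List of [whistle()] objects sharing `chain_id` and
#'   `generation`.
#' @return An object of class `whistle_set`.
#' @export
whistle_set <- function(whistles) {
  if (length(whistles) == 0L) stop("a whistle_set needs at least one whistle")
  stopifnot(all(vapply(whistles, inherits, logical(1), "whistle")))
  ch <- unique(vapply(whistles, `[[`, character(1), "chain_id"))
  gen <- unique(vapply(whistles, `[[`, integer(1), "generation"))
  if (length(ch) != 1L || length(gen) != 1L)
    stop("all whistles in a set must share chain_id and generation")
  ids <- vapply(whistles, `[[`, character(1), "whistle_id")
  if (anyDuplicated(ids))
    stop("duplicate whistle_id within a set: ", ids[duplicated(ids)][1])
  structure(list(chain_id = ch, generation = gen, whistles = whistles),
            class = "whistle_set")
}

#' @export
print.whistle_set <- function(x, ...) {
  cat(sprintf("<whistle_set> chain %s gen %d: %d whistles\n",
              x$chain_id, x$generation, length(x$whistles)))
  invisible(x)
}

#' A full transmission-chain dataset
#'
#' @param sets List of [whistle_set()] objects; grouped by chain, ordered by
#'   strictly increasing generation within each chain.
#' @return An object of class `chain_dataset`: a list with element `chains`,
#'   a named list mapping chain_id to its ordered list of sets.
#' @export
chain_dataset <- function(sets = list()) {
  stopifnot(all(vapply(sets, inherits, logical(1), "whistle_set")))
  chains <- split(sets, vapply(sets, `[[`, character(1), "chain_id"))
  chains <- lapply(chains, function(ss) {
    gens <- vapply(ss, `[[`, integer(1), "generation")
    if (anyDuplicated(gens)) stop("duplicate generation within a chain")
    ss[order(gens)]
  })
  structure(list(chains = chains), class = "chain_dataset")
}

#' @export
print.chain_dataset <- function(x, ...) {
  cat(sprintf("<chain_dataset> %d chains: %s\n", length(x$chains),
              paste(vapply(x$chains, length, integer(1)), collapse = ", ")),
      "generations per chain\n")
  invisible(x)
}

#' Iterate over all sets of a chain dataset
#' @param ds A [chain_dataset()].
#' @return Flat list of `whistle_set` objects, chain-major, generation order.
#' @export
dataset_sets <- function(ds) {
  stopifnot(inherits(ds, "chain_dataset"))
  unlist(unname(ds$chains), recursive = FALSE)
}

## ---------------------------------------------------------------- file I/O

#' Read a two-column track CSV
#'
#' Expects header `time_s,value` and a uniform time step (tolerance 1e-6 s).
#' Empty `value` fields are read as absent (`NA`) pitch samples.
#'
#' @param path File path.
#' @param type `"pitch"` or `"intensity"`.
#' @return A [pitch_track()] or [intensity_track()].
#' @export
read_track_csv <- function(path, type = c("pitch", "intensity")) {
  type <- match.arg(type)
  d <- read.csv(path, header = TRUE, colClasses = "numeric")
  if (ncol(d) < 2L) stop("track CSV must have columns time_s,value: ", path)
  t <- d[[1]]; v <- d[[2]]
  if (length(t) < 1L) stop("empty track file: ", path)
  if (length(t) > 1L) {
    dt <- diff(t)
    bad <- which(abs(dt - dt[1]) > 1e-6)
    if (length(bad))
      stop(sprintf("non-uniform sampling in %s at data row %d (step %.6f, expected %.6f)",
                   path, bad[1] + 1L, dt[bad[1]], dt[1]))
    rate <- 1 / dt[1]
  } else rate <- 500
  new_track(v, rate, t[1], type)
}

#' Write a track to CSV
#'
#' Values are written with full precision (`%.17g`) so that a write/read
#' round trip reproduces finite values bit-identically. Absent pitch samples
#' become empty fields.
#'
#' @param track A track object.
#' @param path Output path.
#' @export
write_track_csv <- function(track, path) {
  stopifnot(inherits(track, "wc_track"))
  t <- track_times(track)
  v <- ifelse(is.na(track$values), "", sprintf("%.17g", track$values))
  writeLines(c("time_s,value", paste(sprintf("%.17g", t), v, sep = ",")), path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with columns `chain_id, generation, whistle_id,
#' pitch_file, intensity_file`; file paths are resolved relative to the
#' manifest's directory. Whistles are grouped into sets by (chain,
#' generation).
#'
#' @param path Manifest CSV path.
#' @return A [chain_dataset()]. An empty manifest yields an empty dataset.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, header = TRUE, colClasses = "character")
  need <- c("chain_id", "generation", "whistle_id", "pitch_file", "intensity_file")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (nrow(m) == 0L) return(chain_dataset(list()))
  dir <- dirname(path)
  key <- paste(m$chain_id, m$generation, sep = "\r")
  sets <- lapply(split(seq_len(nrow(m)), key), function(idx) {
    rows <- m[idx, , drop = FALSE]
    if (anyDuplicated(rows$whistle_id))
      stop("duplicate whistle_id within set (", rows$chain_id[1], ", gen ",
           rows$generation[1], "): ",
           rows$whistle_id[duplicated(rows$whistle_id)][1])
    ws <- lapply(seq_len(nrow(rows)), function(i) {
      pf <- file.path(dir, rows$pitch_file[i])
      inf <- file.path(dir, rows$intensity_file[i])
      for (f in c(pf, inf)) if (!file.exists(f))
        stop("missing track file for whistle ", rows$whistle_id[i], ": ", f)
      whistle(rows$whistle_id[i], rows$chain_id[i],
              as.integer(rows$generation[i]),
              read_track_csv(pf, "pitch"),
              read_track_csv(inf, "intensity"))
    })
    whistle_set(ws)
  })
  chain_dataset(unname(sets))
}

#' Write a chain dataset as track CSVs plus a manifest
#'
#' @param ds A [chain_dataset()].
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
write_chain_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "chain_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (set in dataset_sets(ds)) {
    for (w in set$whistles) {
      base <- sprintf("%s_g%02d_%s", w$chain_id, w$generation, w$whistle_id)
      pf <- paste0(base, "_pitch.csv"); inf <- paste0(base, "_intensity.csv")
      write_track_csv(w$pitch, file.path(dir, pf))
      write_track_csv(w$intensity, file.path(dir, inf))
      rows[[length(rows) + 1L]] <-
        data.frame(chain_id = w$chain_id, generation = w$generation,
                   whistle_id = w$whistle_id, pitch_file = pf,
                   intensity_file = inf, stringsAsFactors = FALSE)
    }
  }
  man <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain_id = character(), generation = integer(),
               whistle_id = character(), pitch_file = character(),
               intensity_file = character())
  path <- file.path(dir, "manifest.csv")
  write.csv(man, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Praat short-format PitchTier file
#'
#' Parses the short text format (`"ooTextFile"` / `"PitchTier"` header,
#' xmin, xmax, point count, then time/frequency pairs). Frequencies (Hz) are
#' converted to semitones relative to `ref_hz`. Points must be uniformly
#' spaced, as for [read_track_csv()].
#'
#' @param path PitchTier file path.
#' @param ref_hz Semitone reference frequency.
#' @return A [pitch_track()].
#' @export
read_pitchtier <- function(path, ref_hz = st_ref_default) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln)]
  if (!grepl("ooTextFile", ln[1]) || !grepl("PitchTier", ln[2]))
    stop("not a PitchTier ooTextFile: ", path)
  nums <- suppressWarnings(as.numeric(gsub(".*=\\s*", "", ln[-(1:2)])))
  if (any(is.na(nums))) stop("unparseable numeric line in ", path)
  n <- nums[3]
  if (length(nums) != 3 + 2 * n) stop("point count mismatch in ", path)
  t <- nums[3 + 2 * seq_len(n) - 1]
  f <- nums[3 + 2 * seq_len(n)]
  if (n > 1L) {
    dt <- diff(t)
    bad <- which(abs(dt - dt[1]) > 1e-6)
    if (length(bad))
      stop(sprintf("non-uniform sampling in %s at point %d", path, bad[1] + 1L))
    rate <- 1 / dt[1]
  } else rate <- 500
  pitch_track(hz_to_semitones(f, ref_hz), rate, t[1])
}
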