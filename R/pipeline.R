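## Orchestration: simulate -> measure -> trends, driven by a YAML config
## with a single master seed. Every stage seed is derived deterministically
## from the master seed and the stage/chain/generation tags, so stages are
## independently reproducible and two runs with one seed are byte-identical.

#' Measure-computation parameters
#'
#' @param bin_width_st Chi-square bin width (semitones, default 1).
#' @param k_max Largest mixture size considered (default 10).
#' @param gmm_runs Mixture runs averaged per set (default 100).
#' @param slide_threshold_st Contour slide threshold (default 1).
#' @param n_shuffles Shuffles for the compression ratio (default 100).
#' @param ddtw_threshold Clustering stop distance (default 0.08).
#' @param resample_len DDTW resampling length (default 50).
#' @param entropy_base Entropy log base (default 2).
#' @return List of class `mu_control`.
#' @export
mu_control <- function(bin_width_st = 1, k_max = 10, gmm_runs = 100,
                       slide_threshold_st = 1, n_shuffles = 100,
                       ddtw_threshold = 0.08, resample_len = 50,
                       entropy_base = 2) {
  stopifnot(bin_width_st > 0, k_max >= 1, gmm_runs >= 1,
            slide_threshold_st >= 0, n_shuffles >= 1, ddtw_threshold >= 0,
            resample_len >= 3, entropy_base > 1)
  structure(as.list(environment()), class = "mu_control")
}

#' Compute all universal measures for one whistle set
#'
#' Emits a tidy table: one row per set-level measure (`chi2`,
#' `mean_components`, `n_blocks`, `entropy`, `chunk_strength`,
#' `prop_horizontal` ... `prop_undulating`) and one row per observation for
#' whistle- and segment-level measures (`onset_interval` per consecutive
#' segment pair, `onset_interval_mean` per whistle for the actual and
#' shuffled datasets, `compression_ratio`, `n_segments`,
#' `whistle_duration_s`, `mean_segment_duration_s` per whistle, `n_targets`
#' per segment).
#'
#' @param set A [whistle_set()].
#' @param control A [seg_control()].
#' @param mu A [mu_control()].
#' @param seed Integer seed for the stochastic measures (mixture restarts,
#'   shuffles).
#' @return data.frame with columns `chain_id, generation, whistle_id,
#'   dataset, measure, unit, value`.
#' @export
measure_set <- function(set, control = seg_control(), mu = mu_control(),
                        seed = 1L) {
  stopifnot(inherits(set, "whistle_set"), inherits(mu, "mu_control"))
  ch <- set$chain_id; gen <- set$generation
  row <- function(measure, value, unit = "", whistle_id = NA_character_,
                  dataset = NA_character_)
    data.frame(chain_id = ch, generation = gen, whistle_id = whistle_id,
               dataset = dataset, measure = measure, unit = unit,
               value = value, stringsAsFactors = FALSE)
  out <- list()

  ## MU1/MU2: tone-target distribution
  targets <- collect_tone_targets(set, control)
  if (length(targets) >= 2L) {
    cu <- chi2_uniform(targets, bin_width = mu$bin_width_st)
    out[[length(out) + 1L]] <- row("chi2", cu$chi2)
    out[[length(out) + 1L]] <- row("chi2_df", cu$df)
    gm <- gmm_component_count(targets, k_max = mu$k_max,
                              n_runs = mu$gmm_runs,
                              seed = derive_seed(seed, "gmm", ch, gen))
    out[[length(out) + 1L]] <- row("mean_components", gm$mean_components)
  }

  ## MU3: contour proportions
  props <- contour_proportions(set, control, mu$slide_threshold_st)
  for (lv in names(props))
    out[[length(out) + 1L]] <- row(paste0("prop_", lv), props[[lv]])

  ## MU5/MU6: building blocks
  mm <- motif_measures(set, control, threshold = mu$ddtw_threshold,
                       resample_len = mu$resample_len,
                       smooth_window = control$smooth_window,
                       base = mu$entropy_base)
  out[[length(out) + 1L]] <- row("entropy", mm$entropy, "bits")
  out[[length(out) + 1L]] <- row("n_blocks", mm$n_blocks)
  if (!is.na(mm$chunk_strength))
    out[[length(out) + 1L]] <- row("chunk_strength", mm$chunk_strength)

  ## MU4 + MU7: per-whistle / per-segment observations
  for (w in set$whistles) {
    wid <- w$whistle_id
    iv <- onset_intervals(w, control)
    for (v in iv)
      out[[length(out) + 1L]] <- row("onset_interval", v, "st", wid)
    cr <- compression_ratio(w, n_shuffles = mu$n_shuffles,
                            seed = derive_seed(seed, "shuffle", ch, gen, wid),
                            control = control)
    if (cr$defined) {
      out[[length(out) + 1L]] <- row("onset_interval_mean", cr$mean_actual,
                                     "st", wid, dataset = "actual")
      out[[length(out) + 1L]] <- row("onset_interval_mean", cr$mean_shuffled,
                                     "st", wid, dataset = "shuffled")
      out[[length(out) + 1L]] <- row("compression_ratio",
                                     cr$compression_ratio, "", wid)
    }
    pm <- phrase_measures(w, control)
    out[[length(out) + 1L]] <- row("n_segments", pm$n_segments, "", wid)
    out[[length(out) + 1L]] <- row("whistle_duration_s",
                                   pm$whistle_duration_s, "s", wid)
    out[[length(out) + 1L]] <- row("mean_segment_duration_s",
                                   pm$mean_segment_duration_s, "s", wid)
    for (s in annotate_whistle(w, control))
      out[[length(out) + 1L]] <- row("n_targets", nrow(s$targets), "",
                                     sprintf("%s.s%d", wid, s$index))
  }
  do.call(rbind, out)
}

#' Compute measures for every set of a chain dataset
#'
#' @param ds A [chain_dataset()].
#' @inheritParams measure_set
#' @return Row-bound measure table (see [measure_set()]).
#' @export
measure_chain_dataset <- function(ds, control = seg_control(),
                                  mu = mu_control(), seed = 1L) {
  do.call(rbind, lapply(dataset_sets(ds), measure_set, control = control,
                        mu = mu, seed = seed))
}

## ------------------------------------------------------------------ config

default_config <- function() {
  list(
    seed = 1L,
    paths = list(input = ".", output = "."),
    simulate = list(n_chains = 4L, n_generations = 10L,
                    start = list(), end = NULL),
    segmentation = list(silence_frac = 0.1, min_gap_s = 0.02,
                        min_segment_s = 0.05, smooth_window = 5L,
                        min_prominence_st = 0.5),
    measures = list(bin_width_st = 1, k_max = 10L, gmm_runs = 100L,
                    slide_threshold_st = 1, n_shuffles = 100L,
                    ddtw_threshold = 0.08, resample_len = 50L,
                    entropy_base = 2)
  )
}

merge_checked <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop("unknown config key: ", full)
    if (is.list(defaults[[key]]) && !is.null(user[[key]]) &&
        !(full %in% c("simulate.start", "simulate.end")))
      defaults[[key]] <- merge_checked(defaults[[key]], user[[key]], full)
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' @param config Path to a YAML file, or a list of overrides. Unknown keys
#'   are rejected with an error naming the key. `simulate.start` /
#'   `simulate.end` hold [generator_params()] overrides.
#' @return Full config list of class `pipeline_config`.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "pipeline_config")) return(config)
  stopifnot(is.list(config))
  cf <- merge_checked(default_config(), config)
  gp_ok <- names(formals(generator_params))
  for (side in c("start", "end")) {
    ov <- cf$simulate[[side]]
    if (!is.null(ov)) {
      bad <- setdiff(names(ov), gp_ok)
      if (length(bad)) stop("unknown config key: simulate.", side, ".", bad[1])
    }
  }
  structure(cf, class = "pipeline_config")
}

config_seg_control <- function(cf)
  do.call(seg_control, cf$segmentation)

config_mu_control <- function(cf)
  do.call(mu_control, cf$measures)

config_fingerprint <- function(cf) {
  cf <- unclass(cf)
  cf$paths <- NULL  # analysis parameters only, not run locations
  sprintf("%08x", derive_seed(0, paste(deparse(cf), collapse = "")))
}

## ---------------------------------------------------------------- commands

#' Simulate a synthetic dataset to disk
#'
#' Builds a [chain_plan()] from the config (`simulate.start` /
#' `simulate.end` generator overrides; a missing `end` means a constant
#' plan), generates the dataset, and writes track CSVs, `manifest.csv`,
#' `ground_truth.csv` and `planted.csv` into `paths.output`.
#'
#' @param config Path, list or `pipeline_config`.
#' @return The output directory, invisibly.
#' @export
pipeline_simulate <- function(config = list()) {
  cf <- load_config(config)
  mk <- function(ov) do.call(generator_params, ov)
  start <- mk(cf$simulate$start)
  end <- if (is.null(cf$simulate$end)) start else mk(cf$simulate$end)
  plan <- chain_plan(start, end, cf$simulate$n_generations,
                     cf$simulate$n_chains)
  res <- generate_chain_dataset(plan, seed = derive_seed(cf$seed, "simulate"))
  out <- cf$paths$output
  write_chain_dataset(res$dataset, out)
  write.csv(res$ground_truth, file.path(out, "ground_truth.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(res$planted, file.path(out, "planted.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(out)
}

#' Measure a dataset on disk
#'
#' Reads `manifest.csv` from `paths.input`, computes all measures, and
#' writes `measures.csv` (run metadata embedded as `#` header comments)
#' into `paths.output`.
#'
#' @param config Path, list or `pipeline_config`.
#' @return The measure table, invisibly.
#' @export
pipeline_measure <- function(config = list()) {
  cf <- load_config(config)
  ds <- read_manifest(file.path(cf$paths$input, "manifest.csv"))
  tab <- measure_chain_dataset(ds, config_seg_control(cf),
                               config_mu_control(cf),
                               seed = derive_seed(cf$seed, "measure"))
  out <- file.path(cf$paths$output, "measures.csv")
  dir.create(cf$paths$output, recursive = TRUE, showWarnings = FALSE)
  con <- file(out, "w")
  writeLines(c(sprintf("# whistlechain measures v1"),
               sprintf("# config %s seed %d", config_fingerprint(cf),
                       as.integer(cf$seed))), con)
  write.csv(tab, con, row.names = FALSE, quote = FALSE)
  close(con)
  invisible(tab)
}

#' Fit generation trends from a measure table
#'
#' @param config Path, list or `pipeline_config`.
#' @param measures_csv Optional path to a measures CSV (default
#'   `paths.input`/measures.csv). A measure table data.frame is also
#'   accepted.
#' @return Trend report data.frame (written to `paths.output`/trends.csv),
#'   invisibly.
#' @export
pipeline_trends <- function(config = list(), measures_csv = NULL) {
  cf <- load_config(config)
  tab <- if (is.data.frame(measures_csv)) measures_csv else {
    path <- if (is.null(measures_csv))
      file.path(cf$paths$input, "measures.csv") else measures_csv
    read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  }
  need <- c("chain_id", "generation", "measure", "value")
  if (!all(need %in% names(tab)))
    stop("measure table lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  rep <- trend_report(tab)
  dir.create(cf$paths$output, recursive = TRUE, showWarnings = FALSE)
  write.csv(rep, file.path(cf$paths$output, "trends.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(rep)
}
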