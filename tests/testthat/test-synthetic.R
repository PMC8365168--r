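test_that("generation is deterministic given a seed", {
  p <- generator_params(n_whistles = 4, seed = 61)
  a <- generate_whistle_set(p)
  b <- generate_whistle_set(p)
  expect_identical(lapply(a$set$whistles, function(w) w$pitch$values),
                   lapply(b$set$whistles, function(w) w$pitch$values))
  expect_identical(a$ground_truth, b$ground_truth)
  c <- generate_whistle_set(generator_params(n_whistles = 4, seed = 62))
  expect_false(identical(a$set$whistles[[1]]$pitch$values,
                         c$set$whistles[[1]]$pitch$values))
})

test_that("rendered pitch stays inside the instrument range", {
  for (seed in 63:65) {
    p <- generator_params(n_pitch_levels = 0, pitch_noise_sd = 0.3,
                          level_jitter_sd = 1, seed = seed)
    out <- generate_whistle_set(p)
    for (w in out$set$whistles) {
      v <- w$pitch$values[!is.na(w$pitch$values)]
      expect_gte(min(v), hz_to_semitones(450))
      expect_lte(max(v), hz_to_semitones(2500))
    }
  }
})

test_that("infeasible parameters are rejected", {
  expect_error(generator_params(n_pitch_levels = 3, level_spacing_st = 1,
                                level_jitter_sd = 0.5), "infeasible")
  expect_error(generator_params(n_pitch_levels = 8, level_spacing_st = 5),
               "infeasible")
  expect_error(generator_params(contour_mixture = c(horizontal = 1)),
               "named over the six")
})

test_that("noise-free sets are measured back exactly as planted", {
  p <- generator_params(n_pitch_levels = 3, level_jitter_sd = 0,
                        pitch_noise_sd = 0, n_block_types = 3,
                        block_reuse_concentration = 0.5, seed = 66)
  out <- generate_whistle_set(p)
  gt <- out$ground_truth

  # segmentation recovers the planted boundaries exactly
  found <- do.call(rbind, lapply(out$set$whistles, function(w) {
    segs <- segment_whistle(w)
    data.frame(whistle_id = w$whistle_id,
               start_sample = vapply(segs, `[[`, numeric(1), "start_sample"),
               end_sample = vapply(segs, `[[`, numeric(1), "end_sample"))
  }))
  expect_equal(found$start_sample, gt$start_sample)
  expect_equal(found$end_sample, gt$end_sample)

  # contour classification reproduces the planted labels
  i <- 0
  for (w in out$set$whistles) for (s in annotate_whistle(w)) {
    i <- i + 1
    expect_identical(classify_contour(s$targets), gt$contour[i])
  }

  # block clustering reproduces the planted partition
  segs <- unlist(lapply(out$set$whistles, annotate_whistle),
                 recursive = FALSE)
  lab <- cluster_building_blocks(segs)
  expect_equal(mclust::adjustedRandIndex(lab$labels, gt$block), 1)
  expect_equal(shannon_entropy(lab), attr(gt, "planted_entropy"))
})

test_that("discrete-scale targets cluster tightly around the planted levels", {
  p <- generator_params(n_pitch_levels = 2, level_jitter_sd = 0.05,
                        pitch_noise_sd = 0, seed = 67)
  out <- generate_whistle_set(p)
  levels_st <- attr(out$ground_truth, "levels_st")
  expect_length(levels_st, 2)
  tg <- collect_tone_targets(out$set)
  nearest <- vapply(tg, function(v) min(abs(v - levels_st)), numeric(1))
  expect_lt(max(nearest), 0.3)
})

test_that("continuous-mode onset steps match the planted scale", {
  p <- generator_params(n_pitch_levels = 0, n_whistles = 30,
                        segments_per_whistle_mean = 6,
                        onset_interval_scale_st = 2, pitch_noise_sd = 0,
                        seed = 68)
  out <- generate_whistle_set(p)
  iv <- unlist(lapply(out$set$whistles, onset_intervals))
  expect_gte(length(iv), 100)
  expect_equal(mean(iv), 2, tolerance = 0.1 * 2)
})

test_that("planted label entropy tracks the reuse concentration", {
  ent <- vapply(c(0, 1.5, 20), function(conc) {
    p <- generator_params(n_block_types = 4,
                          block_reuse_concentration = conc, seed = 69)
    attr(generate_whistle_set(p)$ground_truth, "planted_entropy")
  }, numeric(1))
  expect_true(all(diff(ent) < 0))
  expect_lt(ent[3], 0.2)     # near-total reuse of one block
  expect_gt(ent[1], 1.5)     # close to uniform over 4 blocks
})

test_that("chain plans interpolate parameters linearly across generations", {
  start <- generator_params(n_pitch_levels = 1,
                            block_reuse_concentration = 0.2)
  end <- generator_params(n_pitch_levels = 4,
                          block_reuse_concentration = 2.5)
  plan <- chain_plan(start, end, n_generations = 10, n_chains = 2)
  ps <- lapply(1:10, function(g) whistlechain:::interp_params(plan, g))
  expect_equal(vapply(ps, `[[`, numeric(1), "n_pitch_levels")[c(1, 10)],
               c(1, 4))
  expect_true(all(diff(vapply(ps, `[[`, numeric(1),
                              "block_reuse_concentration")) > 0))
  conc <- vapply(ps, `[[`, numeric(1), "block_reuse_concentration")
  expect_equal(diff(conc), rep(diff(conc)[1], 9), tolerance = 1e-12)
})

test_that("a full chain dataset is reproducible and correctly shaped", {
  plan <- chain_plan(generator_params(n_whistles = 3), n_generations = 3,
                     n_chains = 2)
  a <- generate_chain_dataset(plan, seed = 70)
  b <- generate_chain_dataset(plan, seed = 70)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_length(dataset_sets(a$dataset), 6)
  expect_identical(names(a$dataset$chains), c("chain1", "chain2"))
  gens <- vapply(a$dataset$chains$chain1, `[[`, integer(1), "generation")
  expect_identical(gens, 1:3)
  expect_equal(nrow(a$planted), 6)
})

test_that("derived seeds are stable, distinct and within integer range", {
  s1 <- derive_seed(1, "set", 1, 1)
  expect_identical(s1, derive_seed(1, "set", 1, 1))
  expect_false(s1 == derive_seed(1, "set", 1, 2))
  expect_false(s1 == derive_seed(2, "set", 1, 1))
  seeds <- vapply(1:500, function(i) derive_seed(42, "x", i), integer(1))
  expect_true(all(seeds > 0 & seeds < 2^31))
  expect_false(anyDuplicated(seeds) > 0)
})

test_that("the unstructured preset renders continuous, reuse-free sets", {
  p <- initial_set_params(seed = 71)
  out <- generate_whistle_set(p)
  expect_equal(p$n_pitch_levels, 0)
  expect_gt(attr(out$ground_truth, "planted_entropy"), 2)
  expect_false("arched" %in% out$ground_truth$contour)
})
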