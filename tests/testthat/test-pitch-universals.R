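test_that("tone targets are collected across all segments of a set", {
  set <- make_set(list(list(contour_piece(c(60, 66, 60)))))
  tg <- collect_tone_targets(set, seg_control(silence_threshold = 1))
  expect_equal(tg, c(60, 66, 60), tolerance = 0.2)

  # endpoint-exclusive mode keeps only interior extrema
  tgi <- collect_tone_targets(set, seg_control(silence_threshold = 1),
                              endpoints = FALSE)
  expect_length(tgi, 1)

  # a silent whistle contributes nothing
  w0 <- whistle("w", "c", 1, pitch_track(rep(40, 50)),
                intensity_track(rep(0, 50)))
  expect_length(collect_tone_targets(whistle_set(list(w0)),
                                     seg_control(silence_threshold = 1)), 0)

  # count conservation: 12 whistles x 1 arched segment -> 3 targets each
  set12 <- make_set(rep(list(list(contour_piece(c(60, 66, 60)))), 12))
  expect_length(collect_tone_targets(set12, seg_control(silence_threshold = 1)),
                36)
})

test_that("chi-square against uniform matches the hand computation", {
  # 30 targets in one bin of a forced 3-bin range: (30-10)^2/10 + 2*10 = 60
  r <- chi2_uniform(runif(30, 0.2, 0.8), bin_width = 1, range = c(0, 3))
  expect_equal(r$chi2, 60)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, pchisq(60, 2, lower.tail = FALSE))

  # equal counts give exactly 0; df is k - 1
  x <- c(0.5, 1.5, 2.5, 3.5)
  r2 <- chi2_uniform(x, bin_width = 1)
  expect_equal(r2$chi2, 0)
  expect_equal(r2$df, 3)
  expect_equal(r2$n_bins, 4)

  # single-bin input is degenerate, not an error
  r3 <- chi2_uniform(c(0.4, 0.6), bin_width = 1)
  expect_true(r3$degenerate)
  expect_equal(r3$chi2, 0)
})

test_that("mixture component count recovers planted cluster numbers", {
  set.seed(31)
  x1 <- rnorm(300, 0, 0.1)
  r1 <- gmm_component_count(x1, k_max = 10, n_runs = 20, seed = 1)
  expect_equal(r1$mean_components, 1, tolerance = 0.2)

  x2 <- c(rnorm(150, 0, 0.3), rnorm(150, 12, 0.3))
  r2 <- gmm_component_count(x2, k_max = 10, n_runs = 20, seed = 1)
  expect_equal(r2$mean_components, 2, tolerance = 0.2)

  # deterministic given the seed
  r2b <- gmm_component_count(x2, k_max = 10, n_runs = 20, seed = 1)
  expect_identical(r2$per_run_components, r2b$per_run_components)

  # k_max is lowered with a warning when targets are scarce
  expect_warning(r3 <- gmm_component_count(rnorm(6), k_max = 10, n_runs = 2,
                                           seed = 1), "lowering")
  expect_lte(max(r3$per_run_components), 5)
})

test_that("mean component count grows with planted separation", {
  set.seed(32)
  means <- vapply(c(0, 4, 12), function(sep) {
    x <- c(rnorm(120, 0, 0.3), rnorm(120, sep, 0.3))
    gmm_component_count(x, k_max = 6, n_runs = 10, seed = 7)$mean_components
  }, numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("few-elements check applies the rounded <= 7 rule", {
  expect_true(few_elements_check(2.0)$pass)
  expect_true(few_elements_check(5.0)$pass)
  expect_false(few_elements_check(7.6)$pass)
  expect_true(few_elements_check(7.4)$pass)   # rounds to 7
  r <- gmm_component_count(c(rnorm(50, 0, 0.2), rnorm(50, 6, 0.2)),
                           k_max = 5, n_runs = 5, seed = 2)
  expect_true(few_elements_check(r)$pass)
})

test_that("contour classification follows the slide/sign-change rules", {
  expect_identical(classify_contour(c(60, 60.1)), "horizontal")
  expect_identical(classify_contour(c(60, 65)), "ascending")
  expect_identical(classify_contour(c(65, 60)), "descending")
  expect_identical(classify_contour(c(60, 66, 61)), "arched")
  expect_identical(classify_contour(c(66, 60, 65)), "u_shaped")
  expect_identical(classify_contour(c(60, 65, 61, 66)), "undulating")
  # sub-threshold wiggles drop out entirely
  expect_identical(classify_contour(c(60, 60.5, 66), slide_threshold = 1),
                   "ascending")
  d <- classify_contour(60)
  expect_identical(as.character(d), "horizontal")
  expect_true(attr(d, "degenerate"))
})

test_that("contour classification is shift-invariant and flips under negation", {
  set.seed(33)
  swap <- c(horizontal = "horizontal", ascending = "descending",
            descending = "ascending", arched = "u_shaped",
            u_shaped = "arched", undulating = "undulating")
  for (rep in 1:50) {
    v <- 60 + cumsum(runif(sample(2:6, 1), -5, 5))
    lab <- classify_contour(v)
    expect_identical(classify_contour(v + 17.3), lab)
    expect_identical(classify_contour(-v), unname(swap[lab]))
  }
})

test_that("contour proportions count segments and sum to one", {
  up <- contour_piece(c(60, 65)); down <- contour_piece(c(65, 60))
  set <- make_set(list(list(up, up), list(up, down)))
  p <- contour_proportions(set, seg_control(silence_threshold = 1))
  expect_equal(p[["ascending"]], 0.75)
  expect_equal(p[["descending"]], 0.25)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  flat <- contour_piece(c(60, 60))
  pf <- contour_proportions(make_set(list(list(flat, flat))),
                            seg_control(silence_threshold = 1))
  expect_equal(pf[["horizontal"]], 1)
})

test_that("onset intervals are magnitudes of consecutive onset differences", {
  expect_equal(onset_intervals(c(60, 67)), 7)
  expect_equal(onset_intervals(c(60, 67, 60)), c(7, 7))
  expect_length(onset_intervals(60), 0)

  w <- make_whistle(list(contour_piece(c(60, 62)), contour_piece(c(67, 64))))
  expect_equal(onset_intervals(w, seg_control(silence_threshold = 1)), 7,
               tolerance = 1e-9)
})

test_that("compression ratio matches the exact permutation expectation", {
  # 2 segments: a permutation cannot change the single difference
  r2 <- compression_ratio(c(60, 67), seed = 1)
  expect_equal(r2$compression_ratio, 1)

  # (0, 10, 0): exact expectation 2/3 (orders 10, 5, 5 -> 20/3 over 10)
  expect_equal(exact_compression_expectation(c(0, 10, 0)), 2 / 3)
  r3 <- compression_ratio(c(0, 10, 0), n_shuffles = 400, seed = 5)
  se <- sd(replicate(50, mean(abs(diff(sample(c(0, 10, 0))))))) /
    sqrt(400) / 10
  expect_lt(abs(r3$compression_ratio - 2 / 3), 3 * max(se, 0.01))

  # degenerate inputs give the undefined marker
  expect_false(compression_ratio(c(5, 5, 5), seed = 1)$defined)
  expect_false(compression_ratio(60, seed = 1)$defined)
})

test_that("compression ratio is invariant to scaling all onsets", {
  set.seed(34)
  onsets <- runif(5, 40, 50)
  a <- compression_ratio(onsets, n_shuffles = 50, seed = 9)$compression_ratio
  b <- compression_ratio(onsets * 3, n_shuffles = 50, seed = 9)$compression_ratio
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("Monte-Carlo compression ratio converges to the enumerated value", {
  set.seed(35)
  for (n in 3:5) {
    onsets <- runif(n, 30, 50)
    exact <- exact_compression_expectation(onsets)
    sims <- replicate(30, mean(abs(diff(onsets[sample.int(n)])))) /
      mean(abs(diff(onsets)))
    se <- sd(sims) / sqrt(500)
    est <- compression_ratio(onsets, n_shuffles = 500,
                             seed = n)$compression_ratio
    expect_lt(abs(est - exact), 3 * max(se, 1e-3))
  }
})

test_that("phrase measures report counts and durations", {
  # segments covering [0, 0.5), [0.7, 1.2), [1.4, 2.0) seconds at 500/s
  w <- make_whistle(list(rep(40, 250), rep(42, 250), rep(41, 300)),
                    gap = 100)
  pm <- phrase_measures(w, seg_control(silence_threshold = 1))
  expect_equal(pm$n_segments, 3)
  expect_equal(pm$whistle_duration_s, 2.0)
  expect_equal(pm$mean_segment_duration_s, mean(c(0.5, 0.5, 0.6)))
  expect_lte(pm$whistle_duration_s, length(w$pitch$values) / 500)

  w1 <- make_whistle(list(rep(40, 250)))
  pm1 <- phrase_measures(w1, seg_control(silence_threshold = 1))
  expect_equal(pm1$n_segments, 1)
  expect_equal(pm1$whistle_duration_s, 0.5)

  w0 <- whistle("w", "c", 1, pitch_track(rep(40, 50)),
                intensity_track(rep(0, 50)))
  pm0 <- phrase_measures(w0, seg_control(silence_threshold = 1))
  expect_false(pm0$defined)
  expect_equal(pm0$n_segments, 0)
})
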