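test_that("replicate aggregation returns the arithmetic mean with a percentile bootstrap CI", {
  same <- aggregate_onsets(rep(25, 50), seed = 1)
  expect_equal(same$mean, 25)
  expect_equal(same$ci_half_width, 0)

  expect_equal(aggregate_onsets(c(20, 22, 24), seed = 1)$mean, 22)

  for (seed in 1:10) {
    set.seed(seed + 500)
    vals <- rnorm(30, mean = 25, sd = 2)
    agg <- aggregate_onsets(vals, seed = seed)
    expect_gte(mean(vals), agg$ci_lower)
    expect_lte(mean(vals), agg$ci_upper)
  }
  # same seed, same interval
  expect_identical(aggregate_onsets(c(1, 5, 9, 2), seed = 7),
                   aggregate_onsets(c(1, 5, 9, 2), seed = 7))
  expect_error(aggregate_onsets(25), class = "tagmelt_invalid_argument")
})

test_that("the convergence trace shrinks the bootstrap error as replicates accumulate", {
  trace <- convergence_trace(rep(25, 20), seed = 1)
  expect_equal(trace$running_error, rep(0, 19))
  expect_equal(trace$n, 2:20)

  # the error at n = 50 is below the error at n = 5 in 19 of these 20
  # draws (an n = 5 bootstrap error is itself noisy); the pooled errors
  # separate cleanly
  errs <- vapply(1:20, function(seed) {
    set.seed(seed + 900)
    onsets <- rnorm(50, mean = 25, sd = 1)
    tr <- convergence_trace(onsets, seed = seed)
    c(at5 = tr$running_error[tr$n == 5], at50 = tr$running_error[tr$n == 50])
  }, numeric(2))
  expect_gte(mean(errs["at50", ] < errs["at5", ]), 0.9)
  expect_lt(median(errs["at50", ]), median(errs["at5", ]) / 2)

  set.seed(77)
  onsets <- rnorm(30, 20, 1.5)
  tr <- convergence_trace(onsets, seed = 3)
  expect_equal(tr$running_mean[nrow(tr)],
               aggregate_onsets(onsets, seed = 99)$mean)
})

test_that("the plateau rule picks the first increase in successive differences", {
  crv <- melting_curve(seq(16, 56, by = 8), c(30, 28.5, 27.5, 27, 26.8, 25.5))
  res <- detect_plateau(crv)
  expect_equal(res$rule_trace, c(1.5, 1.0, 0.5, 0.2, 1.3))
  expect_equal(res$chosen_void_size, 48L)
  expect_equal(res$melting_point, 26.8)
  expect_null(res$manual_override)
})

test_that("equal successive differences never trigger the plateau rule", {
  # "decreases or remains the same": a perfectly linear decline has no
  # increase and no collapse, so the plateau falls to the last point
  crv <- melting_curve(seq(16, 80, by = 8), seq(30, 26, length.out = 9))
  res <- detect_plateau(crv)
  expect_equal(res$chosen_void_size, 80L)
  expect_null(detect_collapse(crv))
})

test_that("a manual override supersedes the rule and is recorded", {
  crv <- melting_curve(seq(16, 80, by = 8), c(30, 28.5, 27.5, 27, 26.8, 25.5,
                                              25.4, 25.3, 25.2))
  res <- detect_plateau(crv, override = 64)
  expect_equal(res$chosen_void_size, 64L)
  expect_equal(res$melting_point, 25.4)
  expect_false(is.null(res$manual_override))
  expect_error(detect_plateau(crv, override = 63),
               class = "tagmelt_invalid_argument")
})

test_that("plateau choice is invariant to a constant temperature shift", {
  crv <- gen_melting_curve(plateau_void = 48, collapse_void = 72,
                           noise_sigma = 0, seed = 1)
  res <- detect_plateau(crv)
  shifted <- melting_curve(crv$void_size, crv$mean_onset + 7.3)
  res2 <- detect_plateau(shifted)
  expect_equal(res2$chosen_void_size, res$chosen_void_size)
  expect_equal(res2$melting_point, res$melting_point + 7.3)
})

test_that("mechanical collapse is flagged on sharp terminal drops only", {
  # gentle 0.5-degree steps then a terminal 5-degree drop
  vals <- c(30, 29.5, 29, 28.5, 28, 27.5, 27, 26.5, 21.5)
  crv <- melting_curve(seq(16, 80, by = 8), vals)
  expect_equal(detect_collapse(crv), 8L)
  expect_null(detect_collapse(crv, factor = Inf))
  gentle <- melting_curve(seq(16, 80, by = 8), seq(30, 26, length.out = 9))
  expect_null(detect_collapse(gentle))
  expect_error(detect_collapse(melting_curve(c(16, 24), c(2, 1))),
               class = "tagmelt_invalid_argument")
})

test_that("the design manifest enumerates the full Cartesian product with distinct seeds", {
  full <- enumerate_design(c("POP-POST", "POP-STOST", "POST-STOST"),
                           seq(0.1, 0.9, by = 0.1), seq(16L, 80L, by = 8L), 50L)
  expect_equal(nrow(full), 12150L)
  expect_equal(anyDuplicated(full$seed), 0L)
  expect_equal(anyDuplicated(full[, c("pair", "ratio", "void_size", "replicate")]), 0L)

  expect_equal(nrow(enumerate_design("a", 0.5, 16L, 1L)), 1L)
  expect_equal(nrow(enumerate_design(c("a", "b"), c(0.2, 0.8), c(16L, 24L), 2L)), 16L)
  expect_error(enumerate_design(character(0), 0.5, 16L, 1L),
               class = "tagmelt_invalid_argument")
})
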