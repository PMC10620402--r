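test_that("range filter discards out-of-range intervals, boundaries inclusive", {
  r <- range_filter(rr_series(c(0.6, 0.7, 3.0, 0.65)))
  expect_equal(r$series$intervals, c(0.6, 0.7, 0.65))
  expect_equal(r$report$n_removed_range, 1)

  allin <- rr_series(c(0.7, 0.8, 0.75))
  expect_equal(range_filter(allin)$series$intervals, allin$intervals)

  edge <- range_filter(rr_series(c(0.28, 2.4)))
  expect_length(edge$series$intervals, 2)

  expect_error(range_filter(allin, rr_min = 2, rr_max = 1), "rr_min")
})

test_that("range filter is idempotent", {
  set.seed(2)
  s <- rr_series(stats::runif(200, 0.1, 3))
  once <- range_filter(s)$series
  twice <- range_filter(once)$series
  expect_identical(once$intervals, twice$intervals)
})

test_that("moving-average filter removes only locally deviant beats", {
  const <- rr_series(rep(0.8, 50))
  expect_equal(moving_average_filter(const)$report$n_removed_moving_avg, 0)

  rr <- rep(0.8, 40)
  rr[20] <- 0.8 * 1.3
  r <- moving_average_filter(rr_series(rr))
  expect_equal(which(!r$report$kept_mask), 20)

  rr[20] <- 0.8 * 1.15
  expect_equal(moving_average_filter(rr_series(rr))$report$n_removed_moving_avg, 0)

  expect_error(moving_average_filter(const, window = 4), "odd")
  expect_error(moving_average_filter(const, threshold = 1.5), "threshold")
})

test_that("quotient filter flags jumps against original neighbors", {
  r <- quotient_filter(rr_series(c(0.8, 0.8, 1.2, 0.8)))
  expect_false(r$report$kept_mask[3])   # the 1.2 s beat is removed

  # geometric ramp with 5% steps stays intact
  ramp <- rr_series(0.5 * 1.05^(0:20))
  expect_equal(quotient_filter(ramp)$report$n_removed_quotient, 0)

  # single-pass rule also flags the flanks of an isolated jump
  r2 <- quotient_filter(rr_series(c(0.8, 1.2, 0.8)))
  expect_equal(which(!r2$report$kept_mask), c(1, 2, 3))

  expect_error(quotient_filter(rr_series(c(0.8, 0.9))), "3 beats")
})

test_that("each cleaning rule matches its brute-force definition", {
  set.seed(11)
  s <- quiet_series(400, sd_s = 0.04, seed = 11)
  s <- inject_artifacts(s, n_ectopic = 4, n_outlier = 3, seed = 12)
  rr <- s$intervals
  expect_equal(range_filter(s)$report$kept_mask, oracle_range_keep(rr))
  expect_equal(moving_average_filter(s)$report$kept_mask, oracle_mavg_keep(rr))
  expect_equal(quotient_filter(s)$report$kept_mask, oracle_quotient_keep(rr))
})

test_that("the pipeline removes injected artifacts with few false positives", {
  s <- generate_rr_series("BSL", "adult", duration = 550, seed = 21)
  clean0 <- preprocess_pipeline(s)
  expect_equal(sum(!clean0$report$kept_mask), 0)

  bad <- inject_artifacts(s, n_ectopic = 5, n_outlier = 3, seed = 22)
  idx <- attr(bad, "artifact_idx")
  res <- preprocess_pipeline(bad)
  removed <- which(!res$report$kept_mask)
  expect_true(all(c(idx$ectopic, idx$outlier) %in% removed))
  fp <- setdiff(removed, c(idx$ectopic, idx$outlier))
  expect_lte(length(fp), 2)

  # report counts are consistent with the masks
  expect_equal(res$report$n_input, length(bad$intervals))
  expect_equal(sum(res$report$kept_mask), length(res$series$intervals))

  # beat times are re-accumulated from the survivors (gap closed)
  expect_equal(res$series$beat_times, cumsum(res$series$intervals))
})

test_that("the pipeline signals insufficient data", {
  expect_error(preprocess_pipeline(rr_series(rep(0.8, 20))), "insufficient")
})
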