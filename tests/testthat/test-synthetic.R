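test_that("identical seeds give bitwise-identical series", {
  a <- generate_rr_series("BSL", "young", duration = 300, seed = 9)
  b <- generate_rr_series("BSL", "young", duration = 300, seed = 9)
  expect_identical(a$intervals, b$intervals)
  c <- generate_rr_series("BSL", "young", duration = 300, seed = 10)
  expect_false(identical(a$intervals, c$intervals))
})

test_that("zero-amplitude parameters give a constant series", {
  p <- state_params("young", "BSL")
  p$band_amp <- list(VLF = 0, LF = 0, HF = 0)
  p$one_over_f_amp <- 0
  p$resp_peak$amp <- 0
  p$total_sd <- NULL
  p$shape <- list()
  s <- generate_rr_series("BSL", "young", params = p, duration = 120, seed = 1)
  expect_equal(stats::sd(s$intervals), 0)
  expect_equal(1000 * mean(s$intervals), p$mean_bi)
})

test_that("generated intervals stay physiological and near the state mean", {
  for (g in c("young", "adult")) for (st in c("BSL", "Anesthesia", "ABK")) {
    s <- generate_rr_series(st, g, duration = 600, seed = 7)
    expect_true(all(s$intervals >= 0.28 & s$intervals <= 2.4))
    p <- state_params(g, st)
    expect_lt(abs(1000 * mean(s$intervals) - p$mean_bi), 25)
  }
})

test_that("bad state or age-group labels and durations are rejected", {
  expect_error(generate_rr_series("Sleep", "young"), "unknown state")
  expect_error(generate_rr_series("BSL", "elderly"), "unknown age group")
  expect_error(generate_rr_series("BSL", "young", duration = 0), "positive")
})

test_that("blockade collapses total spectral power by about two orders", {
  bs <- compute_psd(generate_rr_series("BSL", "adult", duration = 600, seed = 3))
  ab <- compute_psd(generate_rr_series("ABK", "adult", duration = 600, seed = 4))
  ratio <- band_powers(ab)$total_power / band_powers(bs)$total_power
  expect_lt(ratio, 1 / 50)
})

test_that("the blockade cohort follows the age law", {
  # noise-free law, single age: target mean is the law's prediction
  law0 <- list(intercept = 515.75, slope = 4.01, noise_sd = 0)
  rec <- generate_abk_cohort(ages = c(40), law = law0, duration = 300,
                             seed = 2)
  expect_lt(abs(1000 * mean(rec[[1]]$series$intervals) - 676.15), 15)

  # null slope: the fitted slope's CI covers zero
  lawnull <- list(intercept = 700, slope = 0, noise_sd = 30)
  coh <- generate_abk_cohort(n = 30, law = lawnull, duration = 300, seed = 3)
  avnn <- vapply(coh, function(r) 1000 * mean(r$series$intervals), numeric(1))
  ages <- vapply(coh, `[[`, numeric(1), "age")
  fit <- fit_age_law(ages, avnn)
  expect_true(fit$ci_slope[1] <= 0 && 0 <= fit$ci_slope[2])

  expect_error(generate_abk_cohort(ages = numeric(0)), "empty")
})

test_that("injected artifacts match their ground truth", {
  s <- quiet_series(600)
  expect_identical(inject_artifacts(s, 0, 0), s)

  bad <- inject_artifacts(s, n_ectopic = 5, n_outlier = 3, seed = 4)
  idx <- attr(bad, "artifact_idx")
  expect_length(idx$ectopic, 10)
  expect_length(idx$outlier, 3)

  # outliers are the only intervals outside the physiological range
  out <- which(bad$intervals < 0.28 | bad$intervals > 2.4)
  expect_setequal(out, idx$outlier)

  # ectopic injection preserves the summed duration of each pair
  clean_only <- inject_artifacts(s, n_ectopic = 5, n_outlier = 0, seed = 4)
  expect_equal(sum(clean_only$intervals), sum(s$intervals), tolerance = 1e-9)

  # exactly the 10 ectopic beats deviate > 20% from their local mean
  dev <- which(!oracle_mavg_keep(clean_only$intervals))
  expect_setequal(dev, attr(clean_only, "artifact_idx")$ectopic)

  expect_error(inject_artifacts(s, n_ectopic = 100, n_outlier = 0), "20%")
})

test_that("cohort grand means sit near the reported state means", {
  coh <- generate_cohort(n_young = 8, n_adult = 0, states = "BSL",
                         duration = 300, seed = 6)
  avnn <- vapply(coh, function(r) 1000 * mean(r$series$intervals), numeric(1))
  se <- stats::sd(avnn) / sqrt(length(avnn))
  expect_lt(abs(mean(avnn) - 680), 3 * se)
})
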