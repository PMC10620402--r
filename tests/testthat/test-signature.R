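test_that("filter specs validate their bands and orders", {
  sp <- signature_spec(list(c(0.05, 0.58)))
  expect_equal(sp$order, 100L)
  expect_equal(sp$window_length, 101L)
  sp2 <- signature_spec(list(c(0.16, 0.58), c(0.015, 0.14)))
  expect_equal(sp2$order, 150L)
  expect_equal(sp2$stop_bands[[1]], c(0.015, 0.14))   # sorted
  expect_error(signature_spec(list(c(0.2, 0.1))), "low < high")
  expect_error(signature_spec(list(c(0.01, 0.2), c(0.15, 0.3))), "disjoint")
})

test_that("an empty stop-band list designs a pass-through impulse", {
  taps <- design_bandstop(signature_spec(list()), fs = 4)
  expect_equal(sum(taps != 0), 1)
  expect_equal(max(abs(fir_response(taps, c(0, 0.1, 1, 1.9)) - 1)), 0,
               tolerance = 1e-12)
})

test_that("the mono blockade filter meets its response targets", {
  taps <- design_bandstop(signature_spec(list(c(0.05, 0.58))), fs = 4)
  expect_equal(sum(taps), 1, tolerance = 1e-3)              # unit DC gain
  expect_lt(20 * log10(fir_response(taps, 0.3)), -40)       # deep stop band
  expect_gt(20 * log10(fir_response(taps, 0.9)), -1)        # passband
  expect_error(design_bandstop(signature_spec(list(c(0.1, 2.5))), fs = 4),
               "Nyquist")
})

test_that("stop-band attenuation matches an independent fir1 design", {
  taps <- design_bandstop(signature_spec(list(c(0.05, 0.58))), fs = 4)
  ref <- signal::fir1(100, c(0.05, 0.58) / 2, type = "stop",
                      window = signal::blackman(101))
  f <- c(0.2, 0.3, 0.45)
  ours <- fir_response(taps, f, fs = 4)
  theirs <- fir_response(as.numeric(ref), f, fs = 4)
  expect_true(all(ours < 1e-3) && all(theirs < 1e-3))
})

test_that("a dual design approximates the cascade of its mono bands", {
  dual <- design_bandstop(
    signature_spec(list(c(0.015, 0.14), c(0.16, 0.58)), order = 150), fs = 4)
  m1 <- design_bandstop(signature_spec(list(c(0.015, 0.14)), order = 150),
                        fs = 4)
  m2 <- design_bandstop(signature_spec(list(c(0.16, 0.58)), order = 150),
                        fs = 4)
  f <- seq(0.01, 1.9, by = 0.01)
  hd <- fir_response(dual, f)
  hc <- fir_response(m1, f) * fir_response(m2, f)
  expect_gt(stats::cor(hd, hc), 0.98)
  expect_lt(stats::median(abs(hd - hc)), 0.05)
})

test_that("a constant series passes through the filter unchanged", {
  s <- rr_series(rep(0.75, 1500))
  out <- apply_signature(s, "young-abk")
  expect_equal(out$intervals, s$intervals, tolerance = 1e-9)
  expect_length(out$intervals, length(s$intervals))
})

test_that("in-band tones are strongly attenuated with the mean preserved", {
  amp_at <- function(x, tt, f) {
    fit <- stats::lm(x ~ sin(2 * pi * f * tt) + cos(2 * pi * f * tt))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  t <- cumsum(rep(0.8, 1500))
  mid <- 200:1300   # away from edge transients
  # 0.15 Hz sits in the deep interior of the 0.05-0.58 Hz stop band;
  # 0.1 Hz lies at the edge of the Blackman transition, where the
  # published 101-tap design reaches about -39 dB after two passes
  for (case in list(list(f = 0.15, db = -40), list(f = 0.1, db = -35))) {
    s <- rr_series(0.8 + 0.04 * sin(2 * pi * case$f * t), beat_times = t)
    out <- apply_signature(s, "young-abk")
    att <- amp_at(out$intervals[mid], t[mid], case$f) /
      amp_at(s$intervals[mid], t[mid], case$f)
    expect_lt(20 * log10(att), case$db)
    expect_lt(abs(mean(out$intervals) - mean(s$intervals)) * 1000, 1)
    expect_length(out$intervals, length(s$intervals))
  }
})

test_that("filtering is zero phase", {
  s <- generate_rr_series("BSL", "young", duration = 500, seed = 19)
  s <- preprocess_pipeline(s)$series
  out <- apply_signature(s, "young-anesthesia")
  gi <- sanclock:::resample_tachogram(s, 4)
  go <- sanclock:::resample_tachogram(out, 4)
  cc <- stats::ccf(gi$x, go$x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("stop-band energy of the output is a tiny fraction of the input", {
  s <- generate_rr_series("Anesthesia", "young", duration = 900, seed = 20)
  s <- preprocess_pipeline(s)$series
  out <- apply_signature(s, "young-abk")
  pin <- compute_psd(s)
  pout <- compute_psd(out)
  band_pow <- function(sp) sanclock:::trapz_band(sp$freqs, sp$psd, 0.08, 0.55)
  expect_lt(band_pow(pout) / band_pow(pin), 0.01)
})

test_that("grid search tuning behaves deterministically", {
  cfg <- sanclock_defaults()
  pre <- signature_presets(cfg)[["young-abk"]]
  mkpair <- function(seed) {
    src <- preprocess_pipeline(generate_rr_series("Anesthesia", "young",
                                                  duration = 900,
                                                  seed = seed))$series
    tgt <- preprocess_pipeline(generate_rr_series("ABK", "young",
                                                  duration = 900,
                                                  seed = seed + 50))$series
    list(source = src, target = tgt)
  }
  train <- lapply(c(31, 32, 33), mkpair)

  # a one-candidate grid returns that candidate
  only <- tune_filter(train, pre, grid = list(pre$stop_bands),
                      mse_args = list(S = 10, m = 2, r_fraction = 0.2))
  expect_equal(only$stop_bands, pre$stop_bands)

  # when source already equals target, no filtering wins
  self_train <- lapply(train, function(p) list(source = p$source,
                                               target = p$source))
  best <- tune_filter(self_train, pre,
                      grid = list(list(), pre$stop_bands),
                      mse_args = list(S = 10, m = 2, r_fraction = 0.2))
  expect_length(best$stop_bands, 0)

  # the published band wins over detuned alternatives on matched data
  grid <- list(list(c(0.2, 0.5)), list(c(0.05, 0.58)), list(c(0.01, 0.03)))
  won <- tune_filter(train, pre, grid = grid)
  expect_equal(won$stop_bands[[1]], c(0.05, 0.58))

  expect_error(tune_filter(train, pre, grid = list()), "empty")
  expect_error(tune_filter(train[1], pre, grid = grid), "2 training pairs")
})
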