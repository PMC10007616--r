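test_that("analytic envelope of a pure tone is unity and dominates any signal", {
  fs <- 2000
  t <- (0:(fs - 1)) / fs
  ae <- analytic_transform(waveform(cos(2 * pi * 50 * t), fs))
  core <- seq(round(0.05 * fs), round(0.95 * fs))  # away from edges
  expect_lt(max(abs(ae$envelope[core] - 1)), 0.02)
  expect_true(all(ae$envelope >= 0))

  zero <- analytic_transform(waveform(numeric(100), fs))
  expect_equal(zero$envelope, numeric(100))
  expect_equal(zero$phase_cos, numeric(100))

  # chirp: modulus of the analytic signal dominates the real part
  ch <- cos(2 * pi * (30 * t + 60 * t^2))
  aec <- analytic_transform(waveform(ch, fs))
  expect_true(all(aec$envelope >= abs(ch) - 1e-9))
  expect_true(all(abs(aec$phase_cos) <= 1))

  expect_error(analytic_transform(waveform(1, fs)), "2 samples")
})

test_that("envelope filtering boosts supra-threshold regions to the S1 level", {
  fs <- 2000
  t <- (0:(2 * fs - 1)) / fs
  # hand-built analytic envelope: two bursts with peaks 1.0 and 0.4
  env <- exp(-(t - 0.5)^2 / (2 * 0.02^2)) + 0.4 * exp(-(t - 1.3)^2 / (2 * 0.02^2))
  ae <- structure(list(envelope = env, phase_cos = rep(1, length(env)),
                       fs = fs, t0 = 0),
                  class = "analytic_envelope")
  fe <- envelope_filter(ae, delta = 2)
  expect_equal(fe$threshold_value, 2 * mean(fe$mfilt))
  runs <- rle(fe$mfilt > fe$threshold_value)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  region_peaks <- mapply(function(s, e) max(fe$boosted[s:e]),
                         starts[runs$values], ends[runs$values])
  expect_length(region_peaks, 2)
  expect_equal(region_peaks, rep(max(fe$mfilt), 2), tolerance = 1e-12)

  # constant envelope: threshold 2c exceeds c everywhere -> no boost
  cae <- structure(list(envelope = rep(0.7, 1000), phase_cos = rep(0.5, 1000),
                        fs = fs, t0 = 0),
                   class = "analytic_envelope")
  cfe <- envelope_filter(cae, delta = 2)
  expect_equal(cfe$z, cfe$mfilt * 0.5, tolerance = 1e-9)

  # delta = 0: every positive region reaches the global peak
  fe0 <- envelope_filter(ae, delta = 0)
  runs0 <- rle(fe0$mfilt > 0)
  ends0 <- cumsum(runs0$lengths); starts0 <- ends0 - runs0$lengths + 1
  pk0 <- mapply(function(s, e) max(fe0$boosted[s:e]),
                starts0[runs0$values], ends0[runs0$values])
  expect_true(all(abs(pk0 - max(fe0$mfilt)) < 1e-12))

  expect_error(envelope_filter(ae, delta = -1), "nonnegative")
})

test_that("unboosted samples of z never exceed the filtered envelope", {
  g <- generate_recording(synthetic_spec(duration_s = 10, seed = 8))
  ae <- analytic_transform(bandpass(g$recording$pcg))
  fe <- envelope_filter(ae, delta = 2)
  unboosted <- fe$mfilt <= fe$threshold_value
  expect_true(all(abs(fe$z[unboosted]) <= abs(fe$mfilt[unboosted]) + 1e-9))
})

test_that("Shannon entropy kernel matches its closed form and bound", {
  x <- c(0, exp(-1), 1)
  se <- shannon_entropy(x)
  expect_equal(se, c(0, exp(-1), 0), tolerance = 1e-12)

  expect_equal(shannon_entropy(rep(5, 10)), numeric(10))

  set.seed(6)
  for (i in 1:20) {
    se <- shannon_entropy(stats::rnorm(500))
    expect_true(all(se >= 0))
    expect_lte(max(se), exp(-1) + 1e-12)
  }
})

test_that("Savitzky-Golay smoothing reproduces cubics and reduces noise variance", {
  fs <- 2000
  t <- (0:(2 * fs - 1)) / fs
  cubic <- 2 - t + 0.5 * t^2 - 0.1 * t^3
  sm <- smooth_entropy(cubic, fs, window_s = 0.45, polyorder = 3)
  expect_lt(max(abs(sm - cubic)), 1e-8)

  expect_error(smooth_entropy(cubic, fs, window_s = 0.001, polyorder = 3),
               "exceed")

  set.seed(7)
  for (i in 1:10) {
    x <- stats::rnorm(4000)
    expect_lt(stats::var(smooth_entropy(x, fs, 0.05, 3)), stats::var(x))
  }
})

test_that("min-max normalisation maps to [0, 1] with the degenerate rule", {
  expect_equal(normalize_minmax(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_minmax(c(5, 5)), c(0, 0))
  set.seed(8)
  for (i in 1:10) {
    y <- normalize_minmax(stats::rnorm(100))
    expect_equal(range(y), c(0, 1))
  }
})

test_that("impulse thresholding fires on sparse peaks, never on constants", {
  const <- impulse_detect(rep(0.3, 1000), sigma = 5, fs = 2000)
  expect_equal(sum(const$impulse), 0)
  expect_length(const$start_indices, 0)

  pos <- c(0, 0, 0.2, 0.5, 0, 0.1)
  all_on <- impulse_detect(pos, sigma = 0, fs = 2000)
  expect_equal(all_on$impulse, as.integer(pos > 0))

  # three rectangular peaks on a low baseline; oracle: independent
  # rising-edge scan at the same threshold
  nse <- rep(0.01, 3000)
  onsets <- c(500L, 1500L, 2500L)
  for (o in onsets) nse[o:(o + 100)] <- 0.9
  it <- impulse_detect(nse, sigma = 5, fs = 2000)
  expect_identical(it$start_indices, naive_rising_edges(nse, 5 * mean(nse)))
  expect_identical(it$start_indices, onsets)
})

test_that("start points convert to times with offsets, boundaries and merging", {
  it <- structure(list(impulse = c(0L, 0L, 1L, 1L, 0L, 1L),
                       start_indices = c(3L, 6L), fs = 2000, sigma = 5),
                  class = "impulse_train")
  sp <- extract_startpoints(it)
  expect_equal(sp$times, c(0.0010, 0.0025))

  none <- impulse_detect(rep(0.5, 10), sigma = 5, fs = 2000)
  expect_length(extract_startpoints(none)$times, 0)

  first_on <- structure(list(impulse = c(1L, 0L), start_indices = 1L,
                             fs = 2000, sigma = 5),
                        class = "impulse_train")
  expect_equal(extract_startpoints(first_on)$times, 0)

  # merging keeps the first of any cluster closer than the minimum gap
  it2 <- structure(list(impulse = NULL,
                        start_indices = c(1L, 41L, 81L, 1001L), fs = 1000,
                        sigma = 5),
                   class = "impulse_train")
  sp2 <- extract_startpoints(it2, min_gap_s = 0.1)
  expect_equal(sp2$times, c(0, 1))

  sp3 <- extract_startpoints(it2, t0 = 5, min_gap_s = 0.1)
  expect_equal(sp3$times, c(5, 6))
})

test_that("the detection chain is deterministic", {
  g <- generate_recording(synthetic_spec(duration_s = 12, seed = 20))
  cfg <- model_config("III")
  run1 <- run_model(g$recording, cfg)
  run2 <- run_model(g$recording, cfg)
  expect_identical(run1$events, run2$events)
})

test_that("every strong S1 burst yields a nearby candidate (10 noisy seeds)", {
  for (k in 1:10) {
    g <- generate_recording(synthetic_spec(duration_s = 20, hr_bpm = 60 + 2 * k,
                                           snr_db = 20, seed = 400 + k))
    lab <- run_model(g$recording, model_config("III"))
    for (s1 in g$annotations$s1_times)
      expect_lt(min(abs(lab$events$time - s1)), 0.05)
  }
})

test_that("envelope filtering restores the S2/S1 peak ratio the plain chain loses", {
  g <- generate_recording(synthetic_spec(duration_s = 20, hr_bpm = 66,
                                         hr_jitter_pct = 0, s2_amp_ratio = 0.4,
                                         snr_db = 40, seed = 31))
  pcg <- bandpass(g$recording$pcg)
  ae <- analytic_transform(pcg)
  fe <- envelope_filter(ae, delta = 2)
  peak_near <- function(x, times, fs) vapply(times, function(tt) {
    idx <- round(tt * fs) + seq(-80, 80)
    max(abs(x[idx]))
  }, numeric(1))
  fs <- pcg$fs
  r_plain <- median(peak_near(pcg$samples, g$annotations$s2_times, fs)) /
    median(peak_near(pcg$samples, g$annotations$s1_times, fs))
  r_ef <- median(peak_near(fe$z, g$annotations$s2_times, fs)) /
    median(peak_near(fe$z, g$annotations$s1_times, fs))
  expect_lt(r_plain, 0.5)
  expect_gt(r_ef, 0.95)
})
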