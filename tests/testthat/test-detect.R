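test_that("central difference velocity matches hand computations", {
  expect_equal(central_velocity(rep(4, 10), 500), rep(0, 10))
  ramp <- (0:9) * 100 / 500
  expect_equal(central_velocity(ramp, 500), rep(100, 10))
  v <- central_velocity(c(0, 0, 1, 2, 2), 500)
  expect_equal(v[2:4], c(250, 500, 250))
  expect_error(central_velocity(c(1, 2), 500), "3 samples")
})

test_that("hysteresis thresholding opens above 30 and closes below 10 deg/s", {
  rate <- 500
  expect_equal(nrow(threshold_events(rep(25, 100), rate)), 0)
  # dip to 15 between two lobes does not split the event
  v <- c(rep(0, 10), 40, 50, 15, 15, 45, 35, 5, rep(0, 10))
  ev <- threshold_events(v, rate)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 11)
  expect_equal(ev$offset, 17)   # first sample below 10
  # triangular pulse: onset first sample > 30, offset first sample < 10
  tri <- c(seq(0, 60, by = 10), seq(50, 0, by = -10))
  evt <- threshold_events(tri, rate)
  expect_equal(evt$onset, which(tri > 30)[1])
  expect_equal(evt$offset, which(seq_along(tri) > evt$onset & tri < 10)[1])
  # event running past the end is flagged truncated
  ev2 <- threshold_events(c(rep(0, 5), rep(50, 5)), rate)
  expect_true(ev2$truncated)
  expect_error(threshold_events(c(-1, 5), rate), "nonnegative")
})

test_that("post-processing merges close events and discards implausible ones", {
  rate <- 500
  x <- cumsum(rep(0.1, 400)); v <- rep(100, 400)
  mk <- function(onset, offset) data.frame(
    onset = onset, offset = offset, onset_s = (onset - 1) / rate,
    offset_s = (offset - 1) / rate, amplitude = NA_real_,
    peak_velocity = NA_real_, duration = (offset - onset) / rate,
    truncated = FALSE)
  # two events 20 ms (10 samples) apart are merged into one
  ev <- postprocess_events(mk(c(50, 80), c(70, 100)), x, v, rate)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 50); expect_equal(ev$offset, 100)
  # an 8 ms event is removed
  expect_equal(nrow(postprocess_events(mk(50, 54), x, v, rate)), 0)
  # a 950 deg/s event is removed
  vfast <- rep(950, 400)
  expect_equal(nrow(postprocess_events(mk(50, 80), x, vfast, rate)), 0)
  # an event within 10 samples of a blink is removed
  blink <- rep(FALSE, 400); blink[85] <- TRUE
  expect_equal(nrow(postprocess_events(mk(50, 80), x, v, rate, blink)), 0)
  blink2 <- rep(FALSE, 400); blink2[95] <- TRUE   # 16 samples clear
  expect_equal(nrow(postprocess_events(mk(50, 80), x, v, rate, blink2)), 1)
  expect_error(postprocess_events(mk(c(80, 50), c(100, 70)), x, v, rate),
               "sorted")
})

test_that("post-processing is idempotent and recomputes event descriptors", {
  sim <- simulate_scanpath(n_saccades = 8, rate = 500, sigma = 0.3, seed = 14)
  scan <- detect_saccades(sim$noisy)
  once <- scan$events
  twice <- postprocess_events(once, scan$denoised, scan$speed, 500,
                              sim$noisy$blink, scan$rules)
  expect_equal(twice, once)
  expect_true(all(once$peak_velocity > 0))
  expect_true(all(once$amplitude >= 0))
  expect_true(all(once$duration >= 0.012))
})

test_that("pipeline recovers simulated saccades and stays silent on pure noise", {
  sim <- simulate_scanpath(n_saccades = 5, rate = 500, sigma = 0, seed = 19)
  scan0 <- detect_saccades(sim$clean)
  expect_equal(nrow(scan0$events), 5)
  expect_true(all(abs(scan0$events$onset - sim$truth$onset) <= 2))
  # same scanpath with sigma = 0.4 noise: same five events, no false alarms
  noisy <- add_noise(sim$clean, 0.4, seed = 20)
  scan1 <- detect_saccades(noisy)
  expect_equal(nrow(scan1$events), 5)
  expect_equal(score_events(sim$truth, scan1$events)$f1, 1)
  # pure noise: no detections
  set.seed(22)
  g <- gaze_series(t = (0:2499) / 500, x = rnorm(2500, 0, 0.3), rate = 500)
  expect_equal(nrow(detect_saccades(g)$events), 0)
  # determinism: identical inputs give identical outputs
  expect_identical(detect_saccades(noisy)$events, scan1$events)
})

test_that("every detected event respects the hysteresis semantics", {
  sim <- simulate_scanpath(n_saccades = 10, rate = 500, sigma = 0.5, seed = 23)
  scan <- detect_saccades(sim$noisy)
  for (i in seq_len(nrow(scan$events))) {
    seg <- scan$speed[scan$events$onset[i]:(scan$events$offset[i] - 1)]
    expect_gt(max(seg), 30)
    if (!scan$events$truncated[i])
      expect_lt(scan$speed[scan$events$offset[i]], 10)
  }
})

test_that("blink samples are interpolated and nearby events suppressed", {
  sim <- simulate_scanpath(n_saccades = 4, rate = 500, sigma = 0.2, seed = 31)
  g <- sim$noisy
  # blank out a window straddling the second saccade
  win <- (sim$truth$onset[2] - 5):(sim$truth$onset[2] + 5)
  g$blink[win] <- TRUE
  g$x[win] <- NA
  scan <- detect_saccades(g)
  expect_equal(nrow(scan$events), 3)
})
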