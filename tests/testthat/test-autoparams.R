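test_that("low-pass differentiator passes slow components and rejects fast ones", {
  rate <- 500
  t <- (0:4999) / rate
  expect_lt(max(abs(lowpass_velocity(rep(2, 5000), rate)$velocity)), 1e-3)
  # 1 Hz sinusoid of 1 deg -> velocity amplitude 2*pi deg/s within 5%
  v1 <- lowpass_velocity(sin(2 * pi * t), rate)$velocity
  expect_equal(max(abs(v1[500:4500])), 2 * pi, tolerance = 0.05)
  # 100 Hz sinusoid: response far below the ideal differentiator's 2*pi*100
  v100 <- lowpass_velocity(sin(2 * pi * 100 * t), rate)$velocity
  expect_lt(max(abs(v100[500:4500])), 0.1 * 2 * pi * 100)
  expect_error(lowpass_velocity(rep(0, 100), rate = 15), "Nyquist|cutoff")
})

test_that("signal statistics recover simulator ground truth", {
  spec <- scanpath_spec(500, data.frame(eta = 550, c = 6, A = rep(10, 5),
                                        sign = c(1, -1, 1, 1, -1)),
                        fixation_durations = rep(0.6, 6))
  out <- synthesize_scanpath(spec)
  st <- estimate_stats(out$clean)
  expect_equal(st$n_candidates, 5)
  expect_equal(st$A_hat, 10, tolerance = 0.5)
  expect_gt(st$D_hat, 0.012)
})

test_that("noise level is estimated from centered fixation data", {
  set.seed(21)
  g <- gaze_series(t = (0:4999) / 500, x = rnorm(5000, 5, 0.3), rate = 500)
  st <- estimate_stats(g)
  expect_equal(st$sigma_hat, 0.3, tolerance = 0.02)
  expect_equal(st$n_candidates, 0)
  expect_equal(st$A_hat, 8)   # fallback defaults for a saccade-free record
  expect_equal(st$D_hat, 0.05)
})

test_that("candidate bursts separated by fewer than 20 samples are merged", {
  r <- data.frame(start = c(100L, 160L, 300L), end = c(150L, 200L, 320L))
  m <- sparsacc:::merge_runs(r, gap = 20L)
  expect_equal(nrow(m), 2)
  expect_equal(m$start, c(100L, 300L))
  expect_equal(m$end, c(200L, 320L))
  # gap of exactly 20 samples is not merged
  r2 <- data.frame(start = c(100L, 171L), end = c(150L, 200L))
  expect_equal(nrow(sparsacc:::merge_runs(r2, gap = 20L)), 2)
})

test_that("regularization formulas match their stated values and branch continuity", {
  # alpha = 8 sigma at 500 Hz
  expect_identical(set_alpha_beta(list(sigma_hat = 0.5, A_hat = 8, D_hat = 0.05),
                                  500)$alpha, 4)
  # beta prefactor limit: sigma = 1, A = 1, D -> 0 gives beta -> 4 at 500 Hz
  expect_equal(set_alpha_beta(list(sigma_hat = 1, A_hat = 1, D_hat = 1e-9),
                              500)$beta, 4, tolerance = 1e-6)
  # high-rate branch: alpha = (0.0032*1000 + 6.4) * sigma
  expect_equal(set_alpha_beta(list(sigma_hat = 1, A_hat = 8, D_hat = 0.05),
                              1000)$alpha, 9.6)
  # both branches coincide exactly at f = 500
  st <- list(sigma_hat = 0.37, A_hat = 6.3, D_hat = 0.048)
  lo <- set_alpha_beta(st, 500)
  expect_identical(lo$alpha, 0.016 * 500 * st$sigma_hat)
  expect_identical((0.0032 * 500 + 6.4) * st$sigma_hat, lo$alpha)
  expect_identical((0.0016 * 500 + 3.2) * sqrt(st$A_hat) * exp(5 * st$D_hat) * st$sigma_hat,
                   lo$beta)
  # linear scaling in sigma; monotone in A and D
  st2 <- st; st2$sigma_hat <- 2 * st$sigma_hat
  expect_equal(set_alpha_beta(st2, 250)$alpha, 2 * set_alpha_beta(st, 250)$alpha)
  expect_equal(set_alpha_beta(st2, 250)$beta, 2 * set_alpha_beta(st, 250)$beta)
  stA <- st; stA$A_hat <- st$A_hat + 1
  stD <- st; stD$D_hat <- st$D_hat + 0.01
  expect_gt(set_alpha_beta(stA, 750)$beta, set_alpha_beta(st, 750)$beta)
  expect_gt(set_alpha_beta(stD, 750)$beta, set_alpha_beta(st, 750)$beta)
  expect_error(set_alpha_beta(list(sigma_hat = 0.3, A_hat = -1, D_hat = 0.05), 500),
               "invalid")
})

test_that("automatic parameters denoise within 2x of a grid-searched RMSE across regimes", {
  regimes <- list(small_normal = list(eta = 550, A = 3),
                  large_normal = list(eta = 550, A = 15),
                  large_slow = list(eta = 150, A = 15))
  for (rg in regimes) {
    spec <- scanpath_spec(500, data.frame(eta = rg$eta, c = 6, A = rep(rg$A, 4),
                                          sign = c(1, -1, 1, -1)),
                          fixation_durations = rep(0.5, 5))
    out <- synthesize_scanpath(spec)
    noisy <- add_noise(out$clean, 0.3, seed = 33)
    st <- estimate_stats(noisy)
    ab <- set_alpha_beta(st, 500)
    rmse <- function(a, b)
      sqrt(mean((gtv_denoise(noisy$x, a, b)$x_hat - out$clean$x)^2))
    auto <- rmse(ab$alpha, ab$beta)
    grid <- expand.grid(a = c(0.5, 1, 2, 4, 8), b = c(1, 3, 6, 12, 24))
    best <- min(mapply(rmse, grid$a, grid$b))
    expect_lt(auto, 2 * best)
  }
})
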