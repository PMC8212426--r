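test_that("difference operators annihilate low-order polynomials and realize the printed stencils", {
  n <- 9
  expect_equal(as.numeric(diff_operator(1, n) %*% rep(3.2, n)), rep(0, n - 1))
  q <- 2 + 0.5 * (1:n) - 0.3 * (1:n)^2
  expect_equal(as.numeric(diff_operator(3, n) %*% q), rep(0, n - 3))
  # unit impulse picks out the reversed stencil
  e4 <- c(0, 0, 0, 1, 0, 0, 0)
  expect_equal(as.numeric(diff_operator(3, 7) %*% e4), c(1, -3, 3, -1))
  expect_error(diff_operator(3, 3), "n > order")
  expect_error(diff_operator(2, 10), "order")
  # objective uses the same stencils as the operators
  set.seed(1); y <- rnorm(12); x <- rnorm(12)
  expect_equal(gtv_objective(y, x, 1.5, 2.5),
               0.5 * sum((y - x)^2) +
                 1.5 * sum(abs(diff_operator(1, 12) %*% x)) +
                 2.5 * sum(abs(diff_operator(3, 12) %*% x)))
})

test_that("objective evaluates hand-computed cases", {
  expect_equal(gtv_objective(rep(1, 5), rep(1, 5), 2, 3), 0)
  set.seed(2); y <- rnorm(8); x <- rnorm(8)
  expect_equal(gtv_objective(y, x, 0, 0), 0.5 * sum((y - x)^2))
  # n = 2: third-difference term vanishes by construction
  expect_equal(gtv_objective(c(0, 1), c(0, 0), 1, 99), 0.5)
  expect_error(gtv_objective(1:4, 1:5, 1, 1), "length")
})

test_that("one MM step solves the reweighted banded system (dense oracle) and is the identity at alpha=beta=0", {
  set.seed(3)
  n <- 50; y <- cumsum(rnorm(n))
  expect_equal(mm_step(y, y * 0.9, 0, 0), y)
  # dense linear-algebra oracle for the update from x0 = y
  eps <- 1e-10
  w1 <- 1 / (abs(diff(y)) + eps)
  w3 <- 1 / (abs(diff(y, differences = 3)) + eps)
  D1 <- diff_operator(1, n); D3 <- diff_operator(3, n)
  A <- diag(n) + 2 * t(D1) %*% diag(w1) %*% D1 + 5 * t(D3) %*% diag(w3) %*% D3
  expect_equal(mm_step(y, y, 2, 5), as.numeric(solve(A, y)), tolerance = 1e-9)
  # descent across random inputs and configurations
  for (i in 1:20) {
    y <- rnorm(40); x0 <- rnorm(40)
    a <- runif(1, 0, 5); b <- runif(1, 0, 10)
    expect_lte(gtv_objective(y, mm_step(y, x0, a, b), a, b),
               gtv_objective(y, x0, a, b))
  }
  expect_error(mm_step(1:5, c(1, NaN, 3, 4, 5), 1, 1), "finite")
})

test_that("solver trace descends, preserves length and reports convergence", {
  set.seed(4)
  y <- cumsum(rnorm(300, 0, 0.3)) + rnorm(300, 0, 0.2)
  fit <- gtv_denoise(y, alpha = 2, beta = 4)
  expect_s3_class(fit, "gtv_denoise")
  expect_length(fit$x_hat, 300)
  expect_true(all(diff(fit$objective_trace) <= 0))
  expect_equal(fitted(fit) + residuals(fit), y)
  expect_error(gtv_denoise(c(1, 2, NA, 4, 5, 6), 1, 1), "index 3")
  expect_error(gtv_denoise(1:4, 1, 1), "5 samples")
})

test_that("an intermittent piecewise-quadratic signal is a near fixed point at small penalties", {
  t <- seq(0, 1, by = 1 / 500)
  x0 <- ifelse(t < 0.4, 0, ifelse(t < 0.5, 100 * (t - 0.4)^2, 1))
  fit <- gtv_denoise(x0, alpha = 1e-4, beta = 1e-4)
  expect_lt(sqrt(mean((fit$x_hat - x0)^2)), 1e-3)
})

test_that("penalty limits recover the constant mean and the least-squares quadratic", {
  set.seed(5)
  y <- rnorm(60, 3, 1)
  # any TV penalty above the critical value gives exactly the mean
  fit_tv <- gtv_denoise(y, alpha = 1e4, beta = 0, max_iter = 1000, tol = 0)
  expect_equal(fit_tv$x_hat, rep(mean(y), 60), tolerance = 1e-8)
  i <- 1:60
  fit_q <- gtv_denoise(y, alpha = 0, beta = 1e5, max_iter = 3000, tol = 0)
  qls <- fitted(lm(y ~ i + I(i^2)))
  expect_equal(fit_q$x_hat, unname(qls), tolerance = 1e-8)
})

test_that("beta=0 reduces toward exact TV denoising and the exact solution is an MM fixed point", {
  set.seed(6)
  y <- cumsum(rnorm(80)) + rnorm(80)
  lam <- 1.3
  xstar <- tv_exact(y, lam)
  # oracle sanity: exact TV solution beats the MM output's objective or ties
  fit <- gtv_denoise(y, lam, 0, max_iter = 2000, tol = 0)
  expect_lte(gtv_objective(y, xstar, lam, 0),
             gtv_objective(y, fit$x_hat, lam, 0) + 1e-10)
  expect_lt(sqrt(mean((fit$x_hat - xstar)^2)), 1e-3)
  # one MM step from the exact minimizer stays at the minimizer
  step <- mm_step(y, xstar, lam, 0)
  expect_lt(sqrt(mean((step - xstar)^2)), 1e-4)
})

test_that("denoised velocity is essentially zero away from a saccade at sigma = 0.4", {
  # single simulated saccade with the regularization chosen to minimize the
  # RMSE against the noise-free series, then the velocity of the denoised
  # trace away from the saccade's support is essentially zero
  spec <- scanpath_spec(500, data.frame(eta = 550, c = 6, A = 10, sign = 1),
                        fixation_durations = c(1, 1))
  out <- synthesize_scanpath(spec)
  noisy <- add_noise(out$clean, 0.4, seed = 8)
  rmse <- function(a, b)
    sqrt(mean((gtv_denoise(noisy$x, a, b)$x_hat - out$clean$x)^2))
  grid <- expand.grid(a = c(2, 3.2, 5, 8, 12), b = c(2, 5, 10, 20, 40))
  best <- grid[which.min(mapply(rmse, grid$a, grid$b)), ]
  v <- central_velocity(gtv_denoise(noisy$x, best$a, best$b)$x_hat, 500)
  # "away" = more than 100 ms outside the true saccade support: the estimate
  # smears the event boundary by a few tens of ms, which is part of the
  # saccade transition, not of the inter-saccadic fixation
  supp <- which(central_velocity(out$clean$x, 500) != 0)
  away <- rep(TRUE, length(v))
  away[max(1, min(supp) - 50):min(length(v), max(supp) + 50)] <- FALSE
  expect_lt(mean(abs(v[away]) > 1), 0.01)
})
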