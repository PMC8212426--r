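# Independent oracles used to check the implementation. None of these share
# code with the package's solver paths.

# Exact 1-D total variation denoising, argmin 0.5||y-x||^2 + lam*sum|diff(x)|,
# by Condat's direct non-iterative algorithm (running taut-string bounds).
tv_exact <- function(y, lam) {
  N <- length(y)
  if (N <= 1 || lam <= 0) return(y)
  x <- numeric(N)
  k <- k0 <- km <- kp <- 1L
  vmin <- y[1] - lam; vmax <- y[1] + lam
  umin <- lam; umax <- -lam
  repeat {
    while (k < N) {
      if (y[k + 1] + umin < vmin - lam) {          # negative jump certified
        x[k0:km] <- vmin
        k <- k0 <- km <- kp <- km + 1L
        vmin <- y[k]; vmax <- y[k] + 2 * lam
        umin <- lam; umax <- -lam
      } else if (y[k + 1] + umax > vmax + lam) {   # positive jump certified
        x[k0:kp] <- vmax
        k <- k0 <- km <- kp <- kp + 1L
        vmin <- y[k] - 2 * lam; vmax <- y[k]
        umin <- lam; umax <- -lam
      } else {
        k <- k + 1L
        umin <- umin + y[k] - vmin
        umax <- umax + y[k] - vmax
        if (umin >= lam) {
          vmin <- vmin + (umin - lam) / (k - k0 + 1); umin <- lam; km <- k
        }
        if (umax <= -lam) {
          vmax <- vmax + (umax + lam) / (k - k0 + 1); umax <- -lam; kp <- k
        }
      }
    }
    if (umin < 0) {
      x[k0:km] <- vmin
      k <- k0 <- km <- km + 1L
      vmin <- y[k]; umin <- lam; umax <- y[k] + lam - vmax
      if (k == N) { x[N] <- vmin + umin; return(x) }
    } else if (umax > 0) {
      x[k0:kp] <- vmax
      k <- k0 <- kp <- kp + 1L
      vmax <- y[k]; umax <- -lam; umin <- y[k] - lam - vmin
      if (k == N) { x[N] <- vmax + umax; return(x) }
    } else {
      x[k0:N] <- vmin + umin / (k - k0 + 1)
      return(x)
    }
  }
}

# D1' u and D3' u without forming matrices (D3 = D1 D1 D1)
d1t <- function(u) c(0, u) - c(u, 0)
d3t <- function(u) d1t(d1t(d1t(u)))

# General-purpose convex solver (ADMM with split variables for both
# difference penalties; prefactored Cholesky for the x-update) for
# 0.5||y-x||^2 + alpha||D1 x||_1 + beta||D3 x||_1. Independent of the
# package's majorization-minimization path.
admm_gtv <- function(y, alpha, beta, rho = 1, iters = 10000) {
  n <- length(y)
  D1 <- diff(diag(n)); D3 <- diff(diag(n), differences = 3)
  R <- chol(diag(n) + rho * (crossprod(D1) + crossprod(D3)))
  soft <- function(v, t) sign(v) * pmax(abs(v) - t, 0)
  x <- y
  z1 <- diff(x); z3 <- diff(x, differences = 3)
  u1 <- numeric(n - 1); u3 <- numeric(n - 3)
  for (i in seq_len(iters)) {
    rhs <- y + rho * (d1t(z1 - u1) + d3t(z3 - u3))
    x <- backsolve(R, forwardsolve(t(R), rhs))
    d1 <- diff(x); d3 <- diff(x, differences = 3)
    z1 <- soft(d1 + u1, alpha / rho); z3 <- soft(d3 + u3, beta / rho)
    u1 <- u1 + d1 - z1; u3 <- u3 + d3 - z3
  }
  as.numeric(x)
}

# Exhaustive maximum one-to-one overlap matching between two interval lists
# (feasible for a handful of events per list).
max_matching_bruteforce <- function(truth, detected) {
  nt <- nrow(truth); nd <- nrow(detected)
  ov <- function(i, j)
    min(truth$offset_s[i], detected$offset_s[j]) -
    max(truth$onset_s[i], detected$onset_s[j])
  rec <- function(i, used) {
    if (i > nt) return(0L)
    best <- rec(i + 1L, used)
    for (j in seq_len(nd)) {
      if (!used[j] && ov(i, j) > 0) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, rep(FALSE, nd))
}

# minimal event data frame from interval endpoints in seconds
mk_events <- function(onset_s, offset_s, rate = 500) {
  data.frame(onset = as.integer(round(onset_s * rate)) + 1L,
             offset = as.integer(round(offset_s * rate)) + 1L,
             onset_s = onset_s, offset_s = offset_s,
             amplitude = rep(1, length(onset_s)),
             peak_velocity = rep(100, length(onset_s)),
             duration = offset_s - onset_s,
             truncated = rep(FALSE, length(onset_s)))
}

# random non-overlapping sorted event list inside [0, span] seconds
random_event_list <- function(n, span = 1) {
  if (n == 0) return(mk_events(numeric(0), numeric(0)))
  pts <- sort(runif(2 * n, 0, span))
  mk_events(pts[seq(1, 2 * n, by = 2)], pts[seq(2, 2 * n, by = 2)])
}
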