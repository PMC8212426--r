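#' Low-pass differentiated velocity estimate
#'
#' Velocity computed by zero-phase low-pass filtering (second-order
#' Butterworth applied forward and backward, so no time shift of saccade
#' centers) followed by a central difference. The transfer function
#' approximates an ideal differentiator below the cut-off frequency and
#' strongly attenuates noise above it. Used only for the rough candidate
#' scan of [estimate_stats()], not for detection.
#'
#' @param x Position series in degrees.
#' @param rate Sampling rate in Hz (> 2 * cutoff).
#' @param cutoff Cut-off frequency in Hz (default 10).
#' @return A list with `velocity` (deg/s) and `position` (the filtered
#'   trace the velocity was computed from).
#' @export
lowpass_velocity <- function(x, rate, cutoff = 10) {
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency")
  if (rate <= 2 * cutoff) stop("sampling rate must exceed twice the cutoff")
  bf <- signal::butter(2, cutoff / (rate / 2))
  # odd-reflection padding suppresses the start-up transients of the
  # forward-backward pass at the record edges
  n <- length(x)
  np <- min(n - 1, as.integer(ceiling(3 * rate / cutoff)))
  xp <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  xs <- signal::filtfilt(bf, xp)[(np + 1):(np + n)]
  list(velocity = central_velocity(xs, rate), position = xs)
}

#' Estimate noise level and average saccade amplitude/duration
#'
#' A rough candidate-saccade scan used to set the denoiser's regularization
#' weights without user input. On the low-pass velocity ([lowpass_velocity()]),
#' candidate saccades are intervals where the speed exceeds 10 deg/s;
#' candidates separated by fewer than 20 samples are merged; candidates
#' shorter than 12 ms are dropped. The mean candidate amplitude `A_hat`
#' (displacement of the filtered trace across the candidate) and mean
#' duration `D_hat` are returned, along with the noise level `sigma_hat`:
#' the standard deviation of the raw position during fixation (non-candidate)
#' segments, each segment centered by its own mean to remove drift bias
#' (segments shorter than 50 ms are excluded from the pool).
#'
#' When no candidate survives (e.g. a fixation-only recording), `A_hat` and
#' `D_hat` fall back to 8 deg and 0.05 s, typical of normal saccades.
#'
#' @param g A [gaze_series()].
#' @param cutoff Low-pass cutoff in Hz for the candidate scan.
#' @return A list with `sigma_hat` (deg), `A_hat` (deg), `D_hat` (s) and
#'   `n_candidates`.
#' @export
estimate_stats <- function(g, cutoff = 10) {
  stopifnot(inherits(g, "gaze_series"))
  n <- n_samples(g)
  if (n / g$rate < 1) stop("need at least 1 s of data")
  chans <- gaze_channels(g)
  lp <- apply(chans, 2, function(ch) lowpass_velocity(ch, g$rate, cutoff),
              simplify = FALSE)
  V <- vapply(lp, `[[`, numeric(n), "velocity")
  P <- vapply(lp, `[[`, numeric(n), "position")
  speed <- if (ncol(chans) == 1L) abs(drop(V)) else sqrt(rowSums(V^2))

  cand <- runs_of(speed > 10)
  cand <- merge_runs(cand, gap = 20L)
  if (nrow(cand) > 0)
    cand <- cand[(cand$end - cand$start + 1) / g$rate >= 0.012, , drop = FALSE]

  amps <- durs <- numeric(0)
  if (nrow(cand) > 0) {
    amps <- vapply(seq_len(nrow(cand)), function(i)
      sqrt(sum((P[cand$end[i], ] - P[cand$start[i], ])^2)), numeric(1))
    durs <- (cand$end - cand$start + 1) / g$rate
  }

  # fixation pool: complement of the candidate intervals
  in_cand <- rep(FALSE, n)
  for (i in seq_len(nrow(cand))) in_cand[cand$start[i]:cand$end[i]] <- TRUE
  fix <- runs_of(!in_cand & !g$blink)
  if (nrow(fix) > 0)
    fix <- fix[(fix$end - fix$start + 1) / g$rate >= 0.05, , drop = FALSE]
  if (nrow(fix) == 0) stop("no fixation samples available to estimate noise")
  centered <- unlist(lapply(seq_len(nrow(fix)), function(i) {
    seg <- chans[fix$start[i]:fix$end[i], , drop = FALSE]
    as.numeric(sweep(seg, 2, colMeans(seg)))
  }))
  sigma_hat <- sd(centered)

  if (length(amps) == 0)
    list(sigma_hat = sigma_hat, A_hat = 8, D_hat = 0.05, n_candidates = 0L)
  else
    list(sigma_hat = sigma_hat, A_hat = mean(amps), D_hat = mean(durs),
         n_candidates = nrow(cand))
}

# runs of TRUE in a logical vector -> data.frame(start, end), 1-based inclusive
runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# merge runs whose gap to the previous run is smaller than `gap` samples
merge_runs <- function(runs, gap) {
  if (nrow(runs) < 2) return(runs)
  out <- runs[1, , drop = FALSE]
  for (i in 2:nrow(runs)) {
    if (runs$start[i] - out$end[nrow(out)] - 1L < gap)
      out$end[nrow(out)] <- runs$end[i]
    else out <- rbind(out, runs[i, , drop = FALSE])
  }
  out
}

#' Automatic setting of the regularization weights
#'
#' Maps the estimated noise level, mean saccade amplitude and mean duration
#' to the denoiser weights, with sampling-rate scaling:
#' for `f <= 500` Hz, `alpha = 0.016 f sigma` and
#' `beta = 0.008 f sqrt(A) exp(5 D) sigma`; for `f > 500` Hz,
#' `alpha = (0.0032 f + 6.4) sigma` and
#' `beta = (0.0016 f + 3.2) sqrt(A) exp(5 D) sigma`. The two branches agree
#' at `f = 500` Hz, where they reduce to `alpha = 8 sigma` and
#' `beta = 4 sqrt(A) exp(5 D) sigma`. `D` is in seconds, so `exp(5 D)` is a
#' mild factor (about 1.1-1.6) for normal saccade durations.
#'
#' @param stats Estimates from [estimate_stats()] (or a list with
#'   `sigma_hat`, `A_hat`, `D_hat`).
#' @param rate Sampling rate in Hz.
#' @return A list with `alpha` and `beta`.
#' @export
#' @examples
#' set_alpha_beta(list(sigma_hat = 0.5, A_hat = 8, D_hat = 0.05), rate = 500)
set_alpha_beta <- function(stats, rate) {
  s <- stats$sigma_hat; A <- stats$A_hat; D <- stats$D_hat
  if (is.null(s) || is.null(A) || is.null(D) ||
      !all(is.finite(c(s, A, D))) || s < 0 || A <= 0 || D <= 0)
    stop("invalid signal statistics")
  if (rate <= 0) stop("sampling rate must be positive")
  if (rate <= 500)
    list(alpha = 0.016 * rate * s,
         beta = 0.008 * rate * sqrt(A) * exp(5 * D) * s)
  else
    list(alpha = (0.0032 * rate + 6.4) * s,
         beta = (0.0016 * rate + 3.2) * sqrt(A) * exp(5 * D) * s)
}
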