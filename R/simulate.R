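#' Soft-ramp function underlying the parametric saccade model
#'
#' A smooth (C^1) approximation to the ramp `max(u, 0)`:
#' `f(u) = u + 0.25 exp(-2u)` for `u >= 0` and `f(u) = 0.25 exp(2u)` for
#' `u <= 0`. Both branches agree at 0 (value 0.25, slope 0.5) and
#' `f(u) - f(-u) = u` for all `u`.
#'
#' @param u Numeric vector (dimensionless).
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' soft_ramp(0)            # 0.25
#' soft_ramp(5) - 5        # ~ 0.25 * exp(-10)
soft_ramp <- function(u) {
  if (any(!is.finite(u))) stop("soft_ramp: input must be finite")
  ifelse(u >= 0, u + 0.25 * exp(-2 * u), 0.25 * exp(2 * u))
}

# derivative of the soft ramp, used for analytic saccade velocities
soft_ramp_deriv <- function(u) {
  ifelse(u >= 0, 1 - 0.5 * exp(-2 * u), 0.5 * exp(2 * u))
}

#' Parameters of one model saccade
#'
#' The parametric saccade model has three parameters: `eta`, the maximum
#' attainable peak angular velocity (deg/s); `c`, the amplitude scale (deg)
#' controlling how quickly peak velocity saturates with amplitude; and `A`,
#' the saccade amplitude (deg). Together `eta` and `c` define the subject's
#' main sequence: the peak velocity of a saccade of amplitude `A` is
#' `eta * (1 - exp(-A/c))`.
#'
#' @param eta Maximum peak angular velocity, deg/s (> 0).
#' @param c Amplitude scale, deg (> 0).
#' @param A Saccade amplitude, deg (> 0).
#' @return An object of class `saccade_params`.
#' @export
saccade_params <- function(eta, c, A) {
  if (!all(is.finite(c(eta, c, A))) || eta <= 0 || c <= 0 || A <= 0)
    stop("saccade_params: eta, c and A must be finite and positive")
  structure(list(eta = eta, c = c, A = A), class = "saccade_params")
}

#' Closed-form peak velocity of a model saccade (main-sequence relation)
#'
#' @param p A [saccade_params()] object.
#' @return Peak velocity in deg/s: `eta * (1 - exp(-A/c))`.
#' @export
#' @examples
#' peak_velocity_closed_form(saccade_params(500, 5, 5))  # 500*(1-exp(-1))
peak_velocity_closed_form <- function(p) {
  stopifnot(inherits(p, "saccade_params"))
  p$eta * (1 - exp(-p$A / p$c))
}

#' Position waveform of one model saccade
#'
#' Evaluates `s(t) = c f(eta (t-onset)/c) - c f(eta (t-onset)/c - A/c)` where
#' `f` is [soft_ramp()]. The waveform rises monotonically from 0 (as
#' `t -> -Inf`) to `A` (as `t -> +Inf`); its midpoint is at
#' `onset + A/(2 eta)`.
#'
#' @param p A [saccade_params()] object.
#' @param t Numeric vector of times in seconds.
#' @param onset Time origin of the saccade in seconds (default 0).
#' @return Displacement in degrees at each `t`.
#' @export
saccade_waveform <- function(p, t, onset = 0) {
  stopifnot(inherits(p, "saccade_params"))
  u <- p$eta * (t - onset) / p$c
  p$c * soft_ramp(u) - p$c * soft_ramp(u - p$A / p$c)
}

# analytic velocity of the model saccade, deg/s
saccade_velocity <- function(p, t, onset = 0) {
  u <- p$eta * (t - onset) / p$c
  p$eta * (soft_ramp_deriv(u) - soft_ramp_deriv(u - p$A / p$c))
}

# Support of the waveform: [t_lo, t_hi] outside of which the waveform is
# within `resid` degrees of its asymptotes. Uses the point symmetry of the
# waveform about t = A/(2 eta): t_hi = A/eta - t_lo.
saccade_support <- function(p, resid = 1e-4) {
  t_mid <- p$A / (2 * p$eta)
  f <- function(t) saccade_waveform(p, t) - resid
  t_left <- t_mid
  while (f(t_left) > 0) t_left <- t_left - max(p$c / p$eta, t_mid)
  t_lo <- stats::uniroot(f, c(t_left, t_mid), tol = 1e-12)$root
  c(lo = t_lo, hi = p$A / p$eta - t_lo)
}

#' Specification of a simulated scanpath
#'
#' Describes a sequence of fixations interleaved with parametric saccades:
#' the sampling rate, the per-saccade model parameters and signs, the
#' fixation durations (one more fixation than saccades), the noise standard
#' deviation and the seed recorded for provenance. [synthesize_scanpath()]
#' renders the specification into a noise-free series with ground truth.
#'
#' @param rate Sampling rate in Hz.
#' @param saccades Data frame with columns `eta`, `c`, `A` (all positive)
#'   and `sign` (+1 or -1), one row per saccade.
#' @param fixation_durations Numeric vector of fixation durations in
#'   seconds, length `nrow(saccades) + 1`, all positive.
#' @param start_position Initial gaze angle in degrees (default 0).
#' @param noise_sigma Noise standard deviation in degrees (metadata;
#'   applied by [add_noise()] or [simulate_scanpath()]).
#' @param seed Integer seed recorded for provenance.
#' @return An object of class `scanpath_spec`.
#' @export
scanpath_spec <- function(rate, saccades, fixation_durations,
                          start_position = 0, noise_sigma = 0, seed = NULL) {
  if (rate <= 0) stop("sampling rate must be positive")
  saccades <- as.data.frame(saccades)
  need <- c("eta", "c", "A", "sign")
  if (nrow(saccades) > 0 && !all(need %in% names(saccades)))
    stop("saccades must have columns eta, c, A, sign")
  if (nrow(saccades) > 0) {
    with(saccades, {
      if (any(eta <= 0 | c <= 0 | A <= 0)) stop("eta, c, A must be positive")
      if (!all(sign %in% c(-1, 1))) stop("sign must be +1 or -1")
    })
  }
  if (length(fixation_durations) != nrow(saccades) + 1)
    stop("need one more fixation duration than saccades")
  if (any(fixation_durations <= 0)) stop("fixation durations must be positive")
  structure(list(rate = rate, saccades = saccades,
                 fixation_durations = as.numeric(fixation_durations),
                 start_position = start_position,
                 noise_sigma = noise_sigma, seed = seed),
            class = "scanpath_spec")
}

#' Render a scanpath specification into a noise-free series with ground truth
#'
#' Fixation segments are exactly constant at the cumulative sum of signed
#' saccade amplitudes; each saccade segment is the model waveform truncated
#' where it is within 1e-4 deg of its asymptotes, so the series is continuous
#' across segment boundaries to below any plausible noise floor. Ground-truth
#' event onsets/offsets are defined by applying the same 30/10 deg/s
#' hysteresis rule used by the detector to the noise-free velocity, so that
#' truth and detections share one convention.
#'
#' @param spec A [scanpath_spec()].
#' @return A list with elements `clean` (a [gaze_series()]) and `truth`
#'   (a saccade-event data frame, see [detect_saccades()]).
#' @export
synthesize_scanpath <- function(spec) {
  stopifnot(inherits(spec, "scanpath_spec"))
  ns <- nrow(spec$saccades)
  supports <- if (ns > 0)
    lapply(seq_len(ns), function(k)
      saccade_support(saccade_params(spec$saccades$eta[k], spec$saccades$c[k],
                                     spec$saccades$A[k])))
  else list()
  # segment durations: fix_1, sacc_1, fix_2, ..., sacc_ns, fix_{ns+1}
  seg_dur <- numeric(2 * ns + 1)
  seg_dur[seq(1, 2 * ns + 1, by = 2)] <- spec$fixation_durations
  if (ns > 0)
    seg_dur[seq(2, 2 * ns, by = 2)] <-
      vapply(supports, function(s) s["hi"] - s["lo"], numeric(1))
  bounds <- c(0, cumsum(seg_dur))
  total <- bounds[length(bounds)]
  n <- floor(total * spec$rate) + 1L
  t <- (seq_len(n) - 1L) / spec$rate
  levels <- spec$start_position +
    c(0, cumsum(spec$saccades$sign * spec$saccades$A))
  seg <- findInterval(t, bounds, rightmost.closed = TRUE)
  x <- numeric(n)
  for (j in seq_len(2 * ns + 1)) {
    idx <- which(seg == j)
    if (!length(idx)) next
    if (j %% 2 == 1) {            # fixation segment j -> level (j+1)/2
      x[idx] <- levels[(j + 1) / 2]
    } else {                      # saccade k = j/2
      k <- j / 2
      p <- saccade_params(spec$saccades$eta[k], spec$saccades$c[k],
                          spec$saccades$A[k])
      tau <- t[idx] - bounds[j] + supports[[k]]["lo"]
      w <- saccade_waveform(p, tau) - saccade_waveform(p, supports[[k]]["lo"])
      x[idx] <- levels[k] + spec$saccades$sign[k] * w
    }
  }
  clean <- gaze_series(t = t, x = x, rate = spec$rate)
  v <- abs(central_velocity(x, spec$rate))
  truth <- threshold_events(v, spec$rate)
  truth <- annotate_events(truth, x, v, spec$rate)
  if (nrow(truth) != ns)
    warning(sprintf("ground truth found %d events for %d simulated saccades",
                    nrow(truth), ns))
  list(clean = clean, truth = truth)
}

#' Add white Gaussian measurement noise to a gaze series
#'
#' Adds i.i.d. zero-mean Gaussian noise of standard deviation `sigma`
#' (degrees) independently to each position channel, modeling eye-tracker
#' measurement noise.
#'
#' @param g A [gaze_series()].
#' @param sigma Noise standard deviation in degrees (>= 0).
#' @param seed Optional integer seed; when given, the result is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A new `gaze_series` with noisy channels.
#' @export
add_noise <- function(g, sigma, seed = NULL) {
  stopifnot(inherits(g, "gaze_series"))
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  with_local_seed(seed, {
    g$x <- g$x + rnorm(length(g$x), 0, sigma)
    if (!is.null(g$y)) g$y <- g$y + rnorm(length(g$y), 0, sigma)
    g
  })
}

#' Simulate a ground-truthed eye-movement recording
#'
#' Convenience wrapper that draws a random scanpath (saccade amplitudes
#' uniform in `amplitude_range` with random signs, fixation durations
#' uniform in `fixation_range`), renders it, and adds measurement noise.
#' The `"normal"` profile uses `eta = 550` deg/s, `c = 6` deg (inside the
#' normative main-sequence band); the `"slow"` profile uses `eta = 150`
#' deg/s, `c = 6` deg, emulating pathologically slow saccades.
#'
#' @param n_saccades Number of saccades.
#' @param rate Sampling rate in Hz.
#' @param sigma Noise standard deviation in degrees.
#' @param profile `"normal"` or `"slow"`, or a list with elements `eta`, `c`
#'   to override.
#' @param amplitude_range Range of saccade amplitudes in degrees.
#' @param fixation_range Range of fixation durations in seconds.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with elements `noisy`, `clean` (both [gaze_series()]),
#'   `truth` (event data frame) and `spec` (the [scanpath_spec()]).
#' @export
#' @examples
#' sim <- simulate_scanpath(n_saccades = 5, rate = 500, sigma = 0.2, seed = 1)
#' nrow(sim$truth)
simulate_scanpath <- function(n_saccades = 50, rate = 500, sigma = 0,
                              profile = "normal",
                              amplitude_range = c(2, 20),
                              fixation_range = c(0.3, 0.8), seed = NULL) {
  pars <- if (is.list(profile)) profile
  else switch(match.arg(profile, c("normal", "slow")),
              normal = list(eta = 550, c = 6),
              slow = list(eta = 150, c = 6))
  with_local_seed(seed, {
    sac <- data.frame(
      eta = rep(pars$eta, n_saccades), c = rep(pars$c, n_saccades),
      A = stats::runif(n_saccades, amplitude_range[1], amplitude_range[2]),
      sign = sample(c(-1, 1), n_saccades, replace = TRUE))
    fix <- stats::runif(n_saccades + 1, fixation_range[1], fixation_range[2])
    spec <- scanpath_spec(rate, sac, fix, noise_sigma = sigma, seed = seed)
    sp <- synthesize_scanpath(spec)
    noisy <- add_noise(sp$clean, sigma)
    list(noisy = noisy, clean = sp$clean, truth = sp$truth, spec = spec)
  })
}
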