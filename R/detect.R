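# Default detection thresholds and post-processing rules. Onset opens at
# 30 deg/s and closes below 10 deg/s because saccadic velocity profiles are
# asymmetric (fast acceleration, slower deceleration); the remaining rules
# discard physiologically implausible detections.
detect_rules <- function(onset_threshold = 30, offset_threshold = 10,
                         min_duration = 0.012, min_isi = 0.040,
                         max_peak_velocity = 800, blink_margin = 10L) {
  stopifnot(onset_threshold > 0, offset_threshold > 0,
            onset_threshold >= offset_threshold,
            min_duration > 0, min_isi > 0, max_peak_velocity > 0,
            blink_margin >= 0)
  list(onset_threshold = onset_threshold, offset_threshold = offset_threshold,
       min_duration = min_duration, min_isi = min_isi,
       max_peak_velocity = max_peak_velocity,
       blink_margin = as.integer(blink_margin))
}

#' Central-difference velocity
#'
#' Computes velocity with the three-point central difference filter
#' (coefficients `[0.5, 0, -0.5]` scaled by the sampling rate):
#' `v[i] = (x[i+1] - x[i-1]) / 2 * rate`. Endpoints use one-sided
#' differences. Exact for linear signals.
#'
#' @param x Numeric position series in degrees (length >= 3).
#' @param rate Sampling rate in Hz.
#' @return Signed velocity in deg/s, same length as `x`.
#' @export
#' @examples
#' central_velocity(c(0, 0, 1, 2, 2), rate = 500)
central_velocity <- function(x, rate) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples for a central difference")
  v <- numeric(n)
  v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2 * rate
  v[1] <- (x[2] - x[1]) * rate
  v[n] <- (x[n] - x[n - 1]) * rate
  v
}

# speed (scalar nonnegative) across one or two channels
channel_speed <- function(chans, rate) {
  V <- apply(chans, 2, central_velocity, rate = rate)
  if (ncol(chans) == 1L) abs(drop(V)) else sqrt(rowSums(V^2))
}

#' Hysteresis velocity thresholding
#'
#' Scans a nonnegative speed series and opens an event at the first sample
#' exceeding `onset_threshold` (default 30 deg/s) outside any open event;
#' the event closes at the first subsequent sample below `offset_threshold`
#' (default 10 deg/s). Events still open at the end of the series close at
#' the last sample and are flagged `truncated`.
#'
#' @param v Nonnegative speed series in deg/s.
#' @param rate Sampling rate in Hz.
#' @param onset_threshold,offset_threshold Hysteresis thresholds in deg/s.
#' @return A data frame of raw events with 1-based sample indices `onset`
#'   (first sample in the event) and `offset` (first sample after the
#'   event, exclusive), times `onset_s`/`offset_s`, `duration` in seconds
#'   and a `truncated` flag. Amplitude and peak velocity are filled in by
#'   the pipeline once the position trace is known.
#' @export
threshold_events <- function(v, rate, onset_threshold = 30,
                             offset_threshold = 10) {
  if (any(v < 0)) stop("speed series must be nonnegative")
  n <- length(v)
  onsets <- integer(0); offsets <- integer(0); trunc <- logical(0)
  open_at <- NA_integer_
  for (i in seq_len(n)) {
    if (is.na(open_at)) {
      if (v[i] > onset_threshold) open_at <- i
    } else if (v[i] < offset_threshold) {
      onsets <- c(onsets, open_at); offsets <- c(offsets, i)
      trunc <- c(trunc, FALSE)
      open_at <- NA_integer_
    }
  }
  if (!is.na(open_at)) {
    onsets <- c(onsets, open_at); offsets <- c(offsets, n)
    trunc <- c(trunc, TRUE)
  }
  data.frame(onset = onsets, offset = offsets,
             onset_s = (onsets - 1) / rate, offset_s = (offsets - 1) / rate,
             amplitude = rep(NA_real_, length(onsets)),
             peak_velocity = rep(NA_real_, length(onsets)),
             duration = (offsets - onsets) / rate, truncated = trunc)
}

# Recompute amplitude (displacement between onset and offset on the
# position trace; Euclidean for two channels) and peak velocity on the
# final event intervals.
annotate_events <- function(ev, chans, speed, rate) {
  if (is.vector(chans)) chans <- cbind(chans)
  ev$onset_s <- (ev$onset - 1) / rate
  ev$offset_s <- (ev$offset - 1) / rate
  ev$duration <- (ev$offset - ev$onset) / rate
  if (nrow(ev) == 0) return(ev)
  for (i in seq_len(nrow(ev))) {
    a <- ev$onset[i]; b <- min(ev$offset[i], nrow(chans))
    ev$amplitude[i] <- sqrt(sum((chans[b, ] - chans[a, ])^2))
    ev$peak_velocity[i] <- max(speed[a:b])
  }
  ev
}

#' Post-processing of detected saccade events
#'
#' Applies, in order: (1) discard events closer than `blink_margin` samples
#' to any blink sample; (2) merge events separated by less than `min_isi`
#' (40 ms; shorter gaps are typically post-saccadic oscillations, not new
#' saccades); (3) discard events shorter than `min_duration` (12 ms);
#' (4) discard events with peak velocity above `max_peak_velocity`
#' (800 deg/s, not physiologically plausible). Amplitude and peak velocity
#' are recomputed on the final intervals. The operation is idempotent.
#'
#' @param ev Event data frame from [threshold_events()], sorted by onset.
#' @param chans Position matrix (one column per channel) the events were
#'   detected on (the denoised trace for the proposed detector).
#' @param speed Nonnegative speed series used for detection.
#' @param rate Sampling rate in Hz.
#' @param blink Logical blink mask (optional).
#' @param rules Rule list from `detect_rules()`.
#' @return The filtered, annotated event data frame.
#' @export
postprocess_events <- function(ev, chans, speed, rate, blink = NULL,
                               rules = detect_rules()) {
  if (is.unsorted(ev$onset)) stop("events must be sorted by onset")
  if (is.vector(chans)) chans <- cbind(chans)
  # (1) blink proximity
  if (!is.null(blink) && any(blink) && nrow(ev) > 0) {
    bidx <- which(blink)
    keep <- vapply(seq_len(nrow(ev)), function(i) {
      d <- pmax(bidx - (ev$offset[i] - 1L), ev$onset[i] - bidx, 0L)
      all(d >= rules$blink_margin)
    }, logical(1))
    ev <- ev[keep, , drop = FALSE]
  }
  # (2) merge events separated by < min_isi
  if (nrow(ev) > 1) {
    merged <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      gap <- (ev$onset[i] - merged$offset[nrow(merged)]) / rate
      if (gap < rules$min_isi) {
        merged$offset[nrow(merged)] <- ev$offset[i]
        merged$truncated[nrow(merged)] <-
          merged$truncated[nrow(merged)] || ev$truncated[i]
      } else merged <- rbind(merged, ev[i, , drop = FALSE])
    }
    ev <- merged
  }
  ev <- annotate_events(ev, chans, speed, rate)
  # (3) minimum duration, (4) peak-velocity plausibility
  if (nrow(ev) > 0) {
    ev <- ev[ev$duration >= rules$min_duration, , drop = FALSE]
    ev <- ev[ev$peak_velocity <= rules$max_peak_velocity, , drop = FALSE]
  }
  rownames(ev) <- NULL
  ev
}

#' Detect saccades by sparse-derivative denoising and velocity thresholding
#'
#' The full detection pipeline: (1) estimate the noise level and average
#' candidate-saccade amplitude/duration from the data and set the
#' regularization weights automatically (unless `alpha`/`beta` are given);
#' (2) denoise each position channel with [gtv_denoise()]; (3) compute the
#' central-difference velocity of the denoised trace; (4) apply hysteresis
#' velocity thresholding (30 deg/s onset, 10 deg/s offset); (5) apply the
#' post-processing rules. Deterministic given its inputs. Samples flagged in
#' the blink mask are linearly interpolated before denoising and events near
#' blinks are discarded in post-processing.
#'
#' @param g A [gaze_series()].
#' @param alpha,beta Optional regularization weights; when `NULL` (default)
#'   they are set automatically from the data ([set_alpha_beta()]).
#' @param rules Threshold/post-processing rules from `detect_rules()`.
#' @param epsilon,max_iter,tol Denoiser settings, see [gtv_denoise()].
#' @return An object of class `saccade_scan`: list with `events` (the event
#'   data frame), `denoised` (matrix of denoised channels), `speed`,
#'   `params` (alpha, beta and, when auto-set, the estimated noise sigma,
#'   mean amplitude and duration), and the input series `g`.
#' @export
#' @examples
#' sim <- simulate_scanpath(n_saccades = 5, sigma = 0.3, seed = 7)
#' scan <- detect_saccades(sim$noisy)
#' scan
detect_saccades <- function(g, alpha = NULL, beta = NULL,
                            rules = detect_rules(), epsilon = 1e-10,
                            max_iter = 100, tol = 1e-8) {
  stopifnot(inherits(g, "gaze_series"))
  gi <- interpolate_blinks(g)
  stats <- NULL
  if (is.null(alpha) || is.null(beta)) {
    stats <- estimate_stats(gi)
    ab <- set_alpha_beta(stats, g$rate)
    if (is.null(alpha)) alpha <- ab$alpha
    if (is.null(beta)) beta <- ab$beta
  }
  chans <- gaze_channels(gi)
  den <- apply(chans, 2, function(ch)
    gtv_denoise(ch, alpha, beta, epsilon, max_iter, tol)$x_hat)
  speed <- channel_speed(den, g$rate)
  ev <- threshold_events(speed, g$rate, rules$onset_threshold,
                         rules$offset_threshold)
  ev <- postprocess_events(ev, den, speed, g$rate, g$blink, rules)
  params <- list(alpha = alpha, beta = beta)
  if (!is.null(stats)) params <- c(params, stats)
  structure(list(events = ev, denoised = den, speed = speed,
                 params = params, rules = rules, g = g,
                 method = "proposed"),
            class = "saccade_scan")
}

# linear interpolation across blink gaps so the solver sees finite input
interpolate_blinks <- function(g) {
  if (!any(g$blink)) return(g)
  fill <- function(x) {
    ok <- !g$blink & is.finite(x)
    if (!any(ok)) stop("no valid samples to interpolate from")
    stats::approx(g$t[ok], x[ok], xout = g$t, rule = 2)$y
  }
  g$x <- fill(g$x)
  if (!is.null(g$y)) g$y <- fill(g$y)
  g
}

#' @export
print.saccade_scan <- function(x, ...) {
  cat(sprintf("Saccade scan (%s detector): %d event(s) in %.2f s of data\n",
              x$method, nrow(x$events), length(x$g$t) / x$g$rate))
  p <- x$params
  if (!is.null(p$alpha))
    cat(sprintf("  alpha = %.4g, beta = %.4g%s\n", p$alpha, p$beta,
                if (!is.null(p$sigma_hat))
                  sprintf(" (auto: sigma = %.3g deg, A = %.3g deg, D = %.3g s, %d candidates)",
                          p$sigma_hat, p$A_hat, p$D_hat, p$n_candidates)
                else ""))
  invisible(x)
}

#' @export
summary.saccade_scan <- function(object, ...) {
  print(object)
  ev <- object$events
  if (nrow(ev) > 0) {
    cat(sprintf("  amplitude: median %.2f deg (range %.2f-%.2f)\n",
                median(ev$amplitude), min(ev$amplitude), max(ev$amplitude)))
    cat(sprintf("  peak velocity: median %.1f deg/s (range %.1f-%.1f)\n",
                median(ev$peak_velocity), min(ev$peak_velocity),
                max(ev$peak_velocity)))
    cat(sprintf("  duration: median %.1f ms\n", 1000 * median(ev$duration)))
  }
  invisible(object)
}

#' @export
plot.saccade_scan <- function(x, ...) {
  g <- x$g
  plot(g$t, g$x, type = "l", col = "grey60", xlab = "time (s)",
       ylab = "gaze angle (deg)", ...)
  lines(g$t, x$denoised[, 1], col = "black", lwd = 1.2)
  ev <- x$events
  if (nrow(ev) > 0) {
    usr <- par("usr")
    rect(ev$onset_s, usr[3], ev$offset_s, usr[4],
         col = grDevices::adjustcolor("grey40", alpha.f = 0.25), border = NA)
  }
  invisible(x)
}
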