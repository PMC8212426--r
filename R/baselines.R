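#' Fixed velocity-threshold baseline detector (VT)
#'
#' The classical baseline: central-difference velocity is computed on the
#' raw (not denoised) position series and contiguous runs of samples whose
#' speed exceeds `threshold` become candidate saccades, which then pass
#' through the same post-processing rules as the proposed detector for a
#' fair comparison. Because raw temporal differentiation amplifies noise,
#' this detector degrades quickly as the noise level grows.
#'
#' @param g A [gaze_series()].
#' @param threshold Velocity threshold in deg/s (default 30, the proposed
#'   method's onset threshold).
#' @param rules Post-processing rules from `detect_rules()`.
#' @return A `saccade_scan` object (see [detect_saccades()]).
#' @export
vt_detect <- function(g, threshold = 30, rules = detect_rules()) {
  stopifnot(inherits(g, "gaze_series"))
  if (threshold <= 0) stop("threshold must be positive")
  gi <- interpolate_blinks(g)
  chans <- gaze_channels(gi)
  speed <- channel_speed(chans, g$rate)
  r <- runs_of(speed > threshold)
  ev <- runs_to_events(r, length(speed), g$rate)
  ev <- postprocess_events(ev, chans, speed, g$rate, g$blink, rules)
  structure(list(events = ev, denoised = chans, speed = speed,
                 params = list(threshold = threshold), rules = rules, g = g,
                 method = "vt"),
            class = "saccade_scan")
}

#' Dispersion-threshold baseline detector (DT / I-DT)
#'
#' Classifies fixations with the classic sliding-window dispersion
#' algorithm: a window of at least `window` seconds is a fixation while its
#' dispersion (max - min per channel, summed over channels) stays at or
#' below `dispersion`; the window is expanded while this holds. Gaps between
#' fixations become saccade events, then pass through the shared
#' post-processing. Defaults (1 deg over 100 ms) follow common I-DT usage.
#'
#' @param g A [gaze_series()].
#' @param dispersion Dispersion threshold in degrees.
#' @param window Minimum fixation window in seconds (>= 2 samples).
#' @param rules Post-processing rules from `detect_rules()`.
#' @return A `saccade_scan` object.
#' @export
dt_detect <- function(g, dispersion = 1, window = 0.1,
                      rules = detect_rules()) {
  stopifnot(inherits(g, "gaze_series"))
  n <- n_samples(g)
  w <- max(2L, as.integer(round(window * g$rate)))
  if (w > n) stop("window longer than the recording")
  gi <- interpolate_blinks(g)
  chans <- gaze_channels(gi)
  disp <- function(a, b) {
    seg <- chans[a:b, , drop = FALSE]
    sum(apply(seg, 2, function(col) max(col) - min(col)))
  }
  is_fix <- rep(FALSE, n)
  i <- 1L
  while (i + w - 1L <= n) {
    j <- i + w - 1L
    if (disp(i, j) <= dispersion) {
      while (j < n && disp(i, j + 1L) <= dispersion) j <- j + 1L
      is_fix[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  r <- runs_of(!is_fix)
  ev <- runs_to_events(r, n, g$rate)
  speed <- channel_speed(chans, g$rate)
  ev <- postprocess_events(ev, chans, speed, g$rate, g$blink, rules)
  structure(list(events = ev, denoised = chans, speed = speed,
                 params = list(dispersion = dispersion, window = window),
                 rules = rules, g = g, method = "dt"),
            class = "saccade_scan")
}

# convert inclusive sample runs to the raw-event data frame layout
runs_to_events <- function(r, n, rate) {
  onsets <- r$start
  offsets <- pmin(r$end + 1L, n)
  keep <- offsets > onsets
  onsets <- onsets[keep]; offsets <- offsets[keep]
  data.frame(onset = onsets, offset = offsets,
             onset_s = (onsets - 1) / rate, offset_s = (offsets - 1) / rate,
             amplitude = rep(NA_real_, length(onsets)),
             peak_velocity = rep(NA_real_, length(onsets)),
             duration = (offsets - onsets) / rate,
             truncated = r$end[keep] == n)
}
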