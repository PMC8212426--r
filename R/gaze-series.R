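#' Construct a gaze position time-series
#'
#' A `gaze_series` holds a uniformly sampled eye-position recording: time in
#' seconds, horizontal (and optionally vertical) gaze angle in degrees, the
#' sampling rate in Hz, and an optional per-sample blink/validity mask.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing
#'   and uniformly spaced at `1/rate`.
#' @param x Horizontal gaze angle in degrees, same length as `t`.
#' @param y Optional vertical gaze angle in degrees.
#' @param rate Sampling rate in Hz. If missing it is inferred from `t`.
#' @param blink Optional logical vector, `TRUE` where the sample is invalid
#'   (blink / track loss). Defaults to all-valid.
#'
#' @return An object of class `gaze_series`: a list with elements `t`, `x`,
#'   optionally `y`, `rate`, and `blink`.
#' @export
#' @examples
#' g <- gaze_series(t = seq(0, 1, by = 0.002), x = rep(0, 501), rate = 500)
#' g
gaze_series <- function(t, x, y = NULL, rate = NULL, blink = NULL) {
  t <- as.numeric(t); x <- as.numeric(x)
  n <- length(t)
  if (n < 2L) stop("a gaze series needs at least two samples")
  if (length(x) != n) stop("t and x must have the same length")
  dt <- diff(t)
  if (any(dt <= 0)) stop("time vector must be strictly increasing")
  if (is.null(rate)) rate <- 1 / median(dt)
  if (rate <= 0) stop("sampling rate must be positive")
  jitter <- max(abs(dt - 1 / rate)) * rate
  if (jitter > 1e-4)
    warning(sprintf("time vector deviates from uniform sampling at %g Hz (max relative jitter %.2g)",
                    rate, jitter))
  if (is.null(blink)) blink <- rep(FALSE, n)
  blink <- as.logical(blink)
  if (length(blink) != n) stop("blink mask length mismatch")
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != n) stop("y length mismatch")
    if (any(!is.finite(y[!blink]))) stop("non-finite y outside blink mask")
  }
  if (any(!is.finite(x[!blink]))) stop("non-finite x outside blink mask")
  structure(list(t = t, x = x, y = y, rate = rate, blink = blink),
            class = "gaze_series")
}

#' @export
print.gaze_series <- function(x, ...) {
  cat(sprintf("Gaze series: %d samples at %g Hz (%.2f s), %s%s\n",
              length(x$t), x$rate, length(x$t) / x$rate,
              if (is.null(x$y)) "1 channel" else "2 channels",
              if (any(x$blink)) sprintf(", %d blink samples", sum(x$blink)) else ""))
  invisible(x)
}

#' @export
plot.gaze_series <- function(x, ...) {
  plot(x$t, x$x, type = "l", xlab = "time (s)", ylab = "gaze angle (deg)", ...)
  if (!is.null(x$y)) lines(x$t, x$y, col = "grey50")
  invisible(x)
}

# number of samples
n_samples <- function(g) length(g$t)

# matrix of position channels, one column per channel
gaze_channels <- function(g) {
  if (is.null(g$y)) cbind(x = g$x) else cbind(x = g$x, y = g$y)
}
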