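#' Event-by-event matching of detections to ground truth
#'
#' A truth event and a detected event match when their time intervals
#' overlap. Matching is one-to-one: truth events are processed in time
#' order and each is paired with the unmatched overlapping detection that
#' ends earliest (ties broken by larger overlap). For interval lists that
#' are each internally non-overlapping this greedy rule attains the maximum
#' possible number of pairs, so one long detection spanning two truth
#' events counts as one true positive and one miss, never two hits.
#'
#' @param truth,detected Event data frames with columns `onset_s` and
#'   `offset_s`, each sorted and internally non-overlapping.
#' @return A list with counts `tp`, `fp`, `fn` and a `pairing` data frame
#'   (`truth` row index, `detected` row index, `overlap` in seconds).
#' @export
match_events <- function(truth, detected) {
  check_event_list <- function(ev, what) {
    if (nrow(ev) < 2) return(invisible())
    if (is.unsorted(ev$onset_s)) stop(what, " events must be sorted")
    if (any(ev$onset_s[-1] < ev$offset_s[-nrow(ev)]))
      stop(what, " events overlap within the list")
  }
  check_event_list(truth, "truth")
  check_event_list(detected, "detected")
  nd <- nrow(detected)
  used <- rep(FALSE, nd)
  pairing <- data.frame(truth = integer(0), detected = integer(0),
                        overlap = numeric(0))
  for (i in seq_len(nrow(truth))) {
    ov <- if (nd > 0)
      pmin(truth$offset_s[i], detected$offset_s) -
      pmax(truth$onset_s[i], detected$onset_s)
    else numeric(0)
    cand <- which(!used & ov > 0)
    if (length(cand)) {
      j <- cand[order(detected$offset_s[cand], -ov[cand])][1]
      used[j] <- TRUE
      pairing <- rbind(pairing,
                       data.frame(truth = i, detected = j, overlap = ov[j]))
    }
  }
  tp <- nrow(pairing)
  list(tp = tp, fp = nd - tp, fn = nrow(truth) - tp, pairing = pairing)
}

#' Event-level detection accuracy metrics
#'
#' Computes precision `tp/(tp+fp)`, recall `tp/(tp+fn)`, their harmonic
#' mean F1, the true-positive rate `tp/n_truth` and false-negative rate
#' `fn/n_truth`. Empty-on-empty (no truth, no detections) is scored as
#' perfect (all ratios 1, fnr 0); detections with no truth give precision 0.
#'
#' @param tp,fp,fn Nonnegative counts.
#' @param n_truth Number of ground-truth events; must equal `tp + fn`.
#' @return A list of class `eval_result` with the counts and the five ratios.
#' @export
#' @examples
#' detection_metrics(tp = 3, fp = 1, fn = 0)
detection_metrics <- function(tp, fp, fn, n_truth = tp + fn) {
  if (any(c(tp, fp, fn) < 0) || n_truth != tp + fn)
    stop("inconsistent counts")
  precision <- if (tp + fp > 0) tp / (tp + fp) else if (n_truth == 0) 1 else 0
  recall <- if (n_truth > 0) tp / n_truth else 1
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  if (tp + fp + fn == 0) f1 <- 1
  tpr <- if (n_truth > 0) tp / n_truth else 1
  fnr <- if (n_truth > 0) fn / n_truth else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, tpr = tpr, fnr = fnr),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("TP %d, FP %d, FN %d | precision %.3f, recall %.3f, F1 %.3f\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Score a detection run against ground truth
#'
#' Convenience wrapper: [match_events()] then [detection_metrics()].
#'
#' @param truth,detected Event data frames.
#' @return An `eval_result`.
#' @export
score_events <- function(truth, detected) {
  m <- match_events(truth, detected)
  detection_metrics(m$tp, m$fp, m$fn)
}

#' Fit the main-sequence relation to a set of saccade events
#'
#' Nonlinear least squares of peak velocity on amplitude under the
#' saturating-exponential main-sequence model
#' `Vp = eta (1 - exp(-A/c))`, where `eta` is the subject's maximum
#' attainable peak velocity and `c` sets the initial slope `eta/c`.
#' Initialized at `eta0 = max(Vp)`, `c0 = median(A)` with a small multi-start
#' fallback grid to avoid local minima.
#'
#' @param events Event data frame with columns `amplitude` (deg) and
#'   `peak_velocity` (deg/s); at least 3 events spanning at least 2
#'   distinct amplitudes.
#' @return An object of class `main_sequence` with `coefficients`
#'   (`eta`, `c`), `fitted`, `residuals` and the data.
#' @export
#' @examples
#' A <- c(2, 5, 10, 15, 20)
#' ev <- data.frame(amplitude = A, peak_velocity = 500 * (1 - exp(-A / 5)))
#' coef(fit_main_sequence(ev))
fit_main_sequence <- function(events) {
  A <- events$amplitude; Vp <- events$peak_velocity
  if (length(A) < 3) stop("need at least 3 events")
  if (length(unique(round(A, 8))) < 2)
    stop("degenerate amplitude spread: need at least 2 distinct amplitudes")
  dat <- data.frame(A = A, Vp = Vp)
  starts <- list(c(eta = max(Vp), c = median(A)))
  for (sc in c(0.5, 2)) for (se in c(1, 1.5))
    starts <- c(starts, list(c(eta = max(Vp) * se, c = median(A) * sc)))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(Vp ~ eta * (1 - exp(-A / c)), data = dat,
                        start = as.list(st),
                        lower = c(eta = 1e-8, c = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("main-sequence fit failed to converge")
  co <- coef(fit)
  structure(list(coefficients = c(eta = unname(co["eta"]), c = unname(co["c"])),
                 fitted = as.numeric(fitted(fit)),
                 residuals = as.numeric(residuals(fit)),
                 data = dat, nls = fit),
            class = "main_sequence")
}

#' @export
print.main_sequence <- function(x, ...) {
  cat(sprintf("Main-sequence fit: Vp = eta (1 - exp(-A/c)), eta = %.1f deg/s, c = %.2f deg\n",
              x$coefficients["eta"], x$coefficients["c"]))
  cat(sprintf("  %d events, residual RMS %.2f deg/s\n",
              nrow(x$data), sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' @export
coef.main_sequence <- function(object, ...) object$coefficients

#' @export
residuals.main_sequence <- function(object, ...) object$residuals

#' @export
predict.main_sequence <- function(object, newdata = NULL, ...) {
  A <- if (is.null(newdata)) object$data$A else newdata$amplitude
  co <- object$coefficients
  co["eta"] * (1 - exp(-A / co["c"]))
}

#' @export
plot.main_sequence <- function(x, ...) {
  plot(x$data$A, x$data$Vp, pch = 20, xlab = "amplitude (deg)",
       ylab = "peak velocity (deg/s)", ...)
  Ag <- seq(min(x$data$A), max(x$data$A), length.out = 200)
  lines(Ag, predict(x, data.frame(amplitude = Ag)))
  invisible(x)
}

#' Simulation benchmark of a detector over a noise grid
#'
#' Regenerates the simulation-study protocol: one random 50-saccade
#' scanpath at the given sampling rate, then for each noise level `sigma`
#' and each replicate an independent white-noise realization, detection,
#' and event-overlap scoring. Fully seeded and reproducible.
#'
#' @param rate Sampling rate in Hz.
#' @param sigmas Noise standard deviations in degrees.
#' @param detector `"proposed"`, `"vt"` or `"dt"`.
#' @param n_saccades Saccades per series.
#' @param n_reps Noise realizations per cell.
#' @param seed Integer seed.
#' @param profile Saccade profile passed to [simulate_scanpath()].
#' @return A data frame with one row per noise level: `sigma`, `rate`,
#'   `f1_mean`, `f1_sd`, `precision`, `recall` (the latter two averaged
#'   over replicates).
#' @export
#' @examples
#' benchmark_detector(rate = 500, sigmas = 0.3, n_saccades = 5, n_reps = 2, seed = 1)
benchmark_detector <- function(rate = 500, sigmas = seq(0.1, 0.9, by = 0.1),
                               detector = c("proposed", "vt", "dt"),
                               n_saccades = 50, n_reps = 10, seed = 1,
                               profile = "normal") {
  detector <- match.arg(detector)
  if (n_reps < 1) stop("n_reps must be >= 1")
  detect_fun <- switch(detector,
                       proposed = detect_saccades,
                       vt = vt_detect,
                       dt = dt_detect)
  base <- simulate_scanpath(n_saccades = n_saccades, rate = rate, sigma = 0,
                            profile = profile, seed = seed)
  rows <- lapply(seq_along(sigmas), function(si) {
    res <- lapply(seq_len(n_reps), function(r) {
      noise_seed <- (seed * 97L + si * 1009L + r * 131L) %% 2147483647L
      noisy <- add_noise(base$clean, sigmas[si], seed = noise_seed)
      scan <- detect_fun(noisy)
      score_events(base$truth, scan$events)
    })
    f1 <- vapply(res, `[[`, numeric(1), "f1")
    data.frame(sigma = sigmas[si], rate = rate,
               f1_mean = mean(f1), f1_sd = sd(f1),
               precision = mean(vapply(res, `[[`, numeric(1), "precision")),
               recall = mean(vapply(res, `[[`, numeric(1), "recall")))
  })
  do.call(rbind, rows)
}
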