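#' Read a gaze time-series from CSV
#'
#' Expects a header with columns `t` (seconds) and `x` (degrees), and
#' optionally `y` (degrees) and `blink` (0/1). Time must be strictly
#' increasing and uniformly spaced; the sampling rate is inferred from the
#' median spacing when not supplied, with a warning on noticeable jitter.
#'
#' @param path Path to the CSV file.
#' @param rate Optional sampling rate in Hz (inferred when `NULL`).
#' @return A [gaze_series()].
#' @export
read_gaze_csv <- function(path, rate = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  if (!all(c("t", "x") %in% names(df)))
    stop("gaze CSV must have columns t and x: ", path)
  bad <- which(!is.finite(df$t))
  if (length(bad)) stop(sprintf("unparseable time value at line %d", bad[1] + 1L))
  nonmono <- which(diff(df$t) <= 0)
  if (length(nonmono))
    stop(sprintf("time not strictly increasing at line %d", nonmono[1] + 2L))
  blink <- if ("blink" %in% names(df)) df$blink != 0 else NULL
  gaze_series(t = df$t, x = df$x, y = df[["y"]], rate = rate, blink = blink)
}

#' Write a gaze time-series to CSV
#'
#' Schema: `t,x[,y],blink` with time in seconds, angles in degrees and
#' blink as 0/1. Round-trips through [read_gaze_csv()].
#'
#' @param g A [gaze_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(g, path) {
  stopifnot(inherits(g, "gaze_series"))
  df <- data.frame(t = g$t, x = g$x)
  if (!is.null(g$y)) df$y <- g$y
  df$blink <- as.integer(g$blink)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# columns of the on-disk event schema (indices are written 0-based,
# half-open, to be language-neutral; in R the data frame uses 1-based
# `onset`/`offset` with the same half-open convention)
events_csv_cols <- c("onset_s", "offset_s", "onset_idx", "offset_idx",
                     "amplitude_deg", "peak_velocity_deg_s", "duration_s")

#' Write saccade events to CSV
#'
#' Schema: `onset_s,offset_s,onset_idx,offset_idx,amplitude_deg,`
#' `peak_velocity_deg_s,duration_s` with 0-based half-open sample indices.
#' An empty event list yields a header-only file. Round-trips through
#' [read_events_csv()].
#'
#' @param events Event data frame (see [detect_saccades()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(onset_s = events$onset_s, offset_s = events$offset_s,
                   onset_idx = events$onset - 1L,
                   offset_idx = events$offset - 1L,
                   amplitude_deg = events$amplitude,
                   peak_velocity_deg_s = events$peak_velocity,
                   duration_s = events$duration)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read saccade events from CSV
#'
#' @param path Path to an events CSV written by [write_events_csv()].
#' @return Event data frame with 1-based half-open `onset`/`offset` indices.
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  if (!all(events_csv_cols %in% names(df)))
    stop("events CSV missing required columns: ", path)
  bad <- which(df$duration_s < 0 | df$offset_idx <= df$onset_idx)
  if (length(bad)) stop(sprintf("invalid event at line %d", bad[1] + 1L))
  data.frame(onset = df$onset_idx + 1L, offset = df$offset_idx + 1L,
             onset_s = df$onset_s, offset_s = df$offset_s,
             amplitude = df$amplitude_deg,
             peak_velocity = df$peak_velocity_deg_s,
             duration = df$duration_s,
             truncated = if ("truncated" %in% names(df)) df$truncated
             else rep(FALSE, nrow(df)))
}
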