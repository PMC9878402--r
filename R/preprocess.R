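#' Zero-phase temporal bandpass filter
#'
#' Applies a Butterworth bandpass (default 0.009-0.08 Hz, the conventional
#' resting-state band) to every ROI timecourse, forward and backward so the
#' filter is zero-phase and window alignment downstream is unaffected.
#'
#' @param ts a [roi_timeseries()].
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1/(2 tr)`.
#' @param order Butterworth order per pass (default 4).
#' @return filtered `roi_ts`, same shape.
#' @export
bandpass <- function(ts, low_hz = 0.009, high_hz = 0.08, order = 4L) {
  stopifnot(inherits(ts, "roi_ts"))
  nyq <- 1 / (2 * ts$tr)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf("bandpass: band [%g, %g] Hz must lie strictly inside (0, Nyquist=%g) Hz",
                 low_hz, high_hz, nyq))
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- ts
  out$data <- t(apply(ts$data, 1L, function(x) signal::filtfilt(bf, x)))
  out
}

#' Discard frames at the head and tail of a run
#'
#' Removes filter edge effects by dropping the first and last frames of a
#' run (38 TRs each side by convention for 1,200-frame acquisitions, giving
#' 1,124 usable frames). The frame offset is updated so retained frames keep
#' their original acquisition indices.
#'
#' @param ts a [roi_timeseries()].
#' @param n_head,n_tail frames to drop at each end.
#' @return trimmed `roi_ts`.
#' @export
trim_frames <- function(ts, n_head = 38L, n_tail = 38L) {
  stopifnot(inherits(ts, "roi_ts"))
  n <- ncol(ts$data)
  if (n_head < 0L || n_tail < 0L) stop("trim_frames: trim counts must be non-negative")
  if (n_head + n_tail >= n)
    stop(sprintf("trim_frames: cannot drop %d + %d frames from a %d-frame run",
                 n_head, n_tail, n))
  keep <- seq.int(n_head + 1L, n - n_tail)
  out <- ts
  out$data <- ts$data[, keep, drop = FALSE]
  out$frame_offset <- ts$frame_offset + as.integer(n_head)
  out
}

#' Framewise displacement from rigid-body motion parameters
#'
#' FD(t) is the sum of absolute frame-to-frame changes of the six
#' realignment parameters, rotations converted to arc length on a sphere of
#' `head_radius` mm (50 mm by convention). FD at the first frame is 0.
#'
#' @param motion frames x 6 matrix: translations (mm) then rotations (rad).
#' @param head_radius sphere radius in mm for the rotation terms.
#' @return numeric vector of per-frame FD in mm.
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  m <- unclass(as.matrix(motion))
  if (ncol(m) != 6L) stop("framewise_displacement: expected 6 motion columns")
  if (nrow(m) < 2L) stop("framewise_displacement: need at least 2 frames")
  d <- abs(diff(m))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + head_radius * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Motion scrub mask
#'
#' Marks as unusable every frame from a high-motion frame (FD above
#' `threshold`) through `n_after` frames later, so that no detection window
#' can include motion-contaminated data.
#'
#' @param fd per-frame framewise displacement (mm).
#' @param threshold FD threshold in mm (default 0.5).
#' @param n_after frames to mask after each supra-threshold frame
#'   (default 30).
#' @return logical vector, `TRUE` = frame unusable.
#' @export
scrub_mask <- function(fd, threshold = 0.5, n_after = 30L) {
  if (threshold <= 0) stop("scrub_mask: threshold must be positive")
  if (n_after < 0L) stop("scrub_mask: n_after must be non-negative")
  n <- length(fd)
  mask <- logical(n)
  for (t in which(fd > threshold)) mask[t:min(n, t + n_after)] <- TRUE
  mask
}

#' Flag runs with too few synchronization events
#'
#' Sessions yielding fewer than `min_ts` detected events (default 60) are
#' excluded from group analyses; a count exactly at the threshold is kept.
#'
#' @param ts_counts named integer vector of per-run event counts.
#' @param min_ts minimum acceptable count.
#' @return data.frame with `run`, `ts_count` and logical `kept`.
#' @export
exclude_low_ts_runs <- function(ts_counts, min_ts = 60L) {
  if (min_ts < 0L) stop("exclude_low_ts_runs: min_ts must be non-negative")
  runs <- if (is.null(names(ts_counts))) as.character(seq_along(ts_counts)) else names(ts_counts)
  data.frame(run = runs, ts_count = as.integer(ts_counts),
             kept = as.integer(ts_counts) >= min_ts, row.names = NULL)
}

#' Z-normalize a window, ROI by ROI
#'
#' Each ROI row is centered and scaled to unit standard deviation within the
#' window, so that window PCA operates on the correlation matrix.
#' Zero-variance rows cannot be scaled; they are set to all-zero and
#' reported via the `"degenerate"` attribute rather than raising an error.
#'
#' @param window ROI x w numeric matrix, `w >= 2`.
#' @return normalized matrix with a logical `"degenerate"` attribute
#'   (one flag per ROI row).
#' @export
window_znorm <- function(window) {
  window <- as.matrix(window)
  w <- ncol(window)
  if (w < 2L) stop("window_znorm: window must have at least 2 frames")
  mu <- rowMeans(window)
  xc <- window - mu
  sdv <- sqrt(rowSums(xc^2) / (w - 1))
  degen <- sdv <= 0 | !is.finite(sdv)
  sdv[degen] <- 1
  z <- xc / sdv
  z[degen, ] <- 0
  attr(z, "degenerate") <- degen
  z
}
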