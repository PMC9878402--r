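#' Enumerate sliding windows
#'
#' Stride-1 windows of odd length `w` over `n_frames` frames, so each window
#' has a well-defined center frame. Indices are 0-based. A `T`-frame run
#' yields `T - w + 1` windows (1,124 frames at w = 25 give 1,100).
#'
#' @param n_frames usable frame count.
#' @param w window length in frames (odd, `w <= n_frames`).
#' @return data.frame with 0-based `start`, `center`, `end`.
#' @export
sliding_windows <- function(n_frames, w) {
  if (w %% 2L == 0L) stop("sliding_windows: window length must be odd so the center is a frame")
  if (w > n_frames) stop(sprintf("sliding_windows: window (%d) exceeds run length (%d)", w, n_frames))
  start <- 0:(n_frames - w)
  data.frame(start = start, center = start + (w - 1L) %/% 2L, end = start + w - 1L)
}

#' Sliding-window PCA over an ROI time series
#'
#' For every stride-1 window the ROI rows are z-normalized within the window
#' ([window_znorm()]) and the first principal component of the windowed
#' matrix is taken, so that the explained variance equals the top eigenvalue
#' of the window correlation matrix divided by its trace (the ROI count for
#' non-degenerate windows). The loadings (unit norm over ROIs) and the
#' score timecourse (projection of the window frames onto the loadings) are
#' kept per window; their overall sign is fixed later by [extract_tsp()].
#'
#' Windows in which every ROI is constant cannot be normalized; they are
#' skipped and flagged.
#'
#' @param ts a filtered, trimmed [roi_timeseries()].
#' @param w window length in frames (odd, default 25; at TR 0.72 s this is
#'   an 18 s window).
#' @return object of class `swpca`: `var` (explained-variance fraction per
#'   window), `centers`/`starts`/`ends` (0-based original-acquisition frame
#'   indices), `loadings` (ROI x windows), `scores` (w x windows),
#'   `skipped` (logical per window), plus bookkeeping fields.
#' @export
swpca <- function(ts, w = 25L) {
  stopifnot(inherits(ts, "roi_ts"))
  if (w < 3L) stop("swpca: window length must be at least 3")
  win <- sliding_windows(ncol(ts$data), w)
  nw <- nrow(win)
  n_roi <- nrow(ts$data)
  var_tc <- rep(NA_real_, nw)
  loadings <- matrix(NA_real_, n_roi, nw)
  scores <- matrix(NA_real_, w, nw)
  skipped <- logical(nw)
  x <- ts$data
  for (i in seq_len(nw)) {
    z <- window_znorm(x[, (win$start[i] + 1L):(win$end[i] + 1L), drop = FALSE])
    degen <- attr(z, "degenerate")
    if (all(degen)) { skipped[i] <- TRUE; next }
    m <- crossprod(z)                       # w x w; same nonzero spectrum as the ROI-space matrix
    e <- eigen(m, symmetric = TRUE)
    e1 <- e$values[1L]
    var_tc[i] <- e1 / sum(diag(m))          # = top eigenvalue / trace of the correlation matrix
    v1 <- e$vectors[, 1L]
    u <- as.vector(z %*% v1) / sqrt(e1)     # unit-norm ROI loadings
    loadings[, i] <- u
    scores[, i] <- sqrt(e1) * v1            # = t(z) %*% u
  }
  structure(list(var = var_tc, starts = win$start + ts$frame_offset,
                 centers = win$center + ts$frame_offset, ends = win$end + ts$frame_offset,
                 loadings = loadings, scores = scores, skipped = skipped, w = as.integer(w),
                 tr = ts$tr, roi_ids = ts$roi_ids, n_frames = ncol(ts$data),
                 frame_offset = ts$frame_offset, subject_id = ts$subject_id,
                 run_id = ts$run_id),
            class = "swpca")
}

#' @export
print.swpca <- function(x, ...) {
  cat(sprintf("<swpca> %d windows of %d frames (%.3g s), %d ROIs; explained variance %.3f-%.3f\n",
              length(x$var), x$w, x$w * x$tr, length(x$roi_ids),
              min(x$var, na.rm = TRUE), max(x$var, na.rm = TRUE)))
  invisible(x)
}

#' Sign-align first-PC loadings with the score slope
#'
#' The sign of a principal component is arbitrary; it is fixed so that the
#' window score timecourse increases toward the synchronization time point.
#' The least-squares slope of the score timecourse serves as the
#' monotonicity surrogate: a negative slope flips both loadings and scores.
#' By default the slope is evaluated over the rising half of the window (up
#' to and including the center frame), where an event transient locked to
#' the window center is strictly increasing; `span = "window"` uses the
#' whole window instead. An exactly zero slope leaves the sign unchanged
#' and flags the event as ambiguous.
#'
#' @param loadings unit-norm ROI loading vector.
#' @param scores w-length score timecourse of the same window.
#' @param span `"half"` (default) or `"window"`: frames used for the slope.
#' @return list with `tsp` (signed unit loadings), `scores` (sign-matched),
#'   `flipped` and `ambiguous` logicals.
#' @export
extract_tsp <- function(loadings, scores, span = c("half", "window")) {
  span <- match.arg(span)
  w <- length(scores)
  idx <- if (span == "half") seq_len((w + 1L) %/% 2L) else seq_len(w)
  tt <- idx - mean(idx)
  slope <- sum(tt * scores[idx]) / sum(tt^2)
  if (slope < 0) list(tsp = -loadings, scores = -scores, flipped = TRUE, ambiguous = FALSE)
  else list(tsp = loadings, scores = scores, flipped = FALSE,
            ambiguous = (slope == 0))
}

#' Detect temporal synchronization events
#'
#' A synchronization event (TS) is a strict local maximum of the sliding
#' window explained-variance timecourse: a window whose first PC explains
#' more variance than both neighboring windows. Endpoint windows are never
#' maxima, plateaus yield no event, and any event whose window overlaps a
#' scrubbed frame is dropped. The signed unit loading vector of each kept
#' event is its temporal synchronization pattern (TSP).
#'
#' @param sw an [swpca()] result.
#' @param mask optional logical scrub mask over the run's frames (in the
#'   same trimmed frame space as the series passed to [swpca()]); see
#'   [scrub_mask()].
#' @param span sign-rule span passed to [extract_tsp()].
#' @return object of class `ts_events`: `events` data.frame (`center`,
#'   `start`, `end` 0-based acquisition frames, `explained_variance`,
#'   `ambiguous`, `sub_cluster` = NA), `tsp` (ROI x events matrix of signed
#'   unit TSPs), and run metadata.
#' @export
detect_ts <- function(sw, mask = NULL, span = c("half", "window")) {
  stopifnot(inherits(sw, "swpca"))
  span <- match.arg(span)
  if (!is.null(mask) && length(mask) != sw$n_frames)
    stop(sprintf("detect_ts: mask length (%d) must match frame count (%d)",
                 length(mask), sw$n_frames))
  v <- sw$var
  n <- length(v)
  is_max <- logical(n)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    ok <- !is.na(v[i]) & !is.na(v[i - 1L]) & !is.na(v[i + 1L])
    is_max[i] <- ok & v[i] > v[i - 1L] & v[i] > v[i + 1L]
  }
  keep <- which(is_max)
  if (!is.null(mask)) {
    masked_frames <- which(mask) - 1L + sw$frame_offset     # 0-based acquisition frames
    keep <- keep[vapply(keep, function(i)
      !any(masked_frames >= sw$starts[i] & masked_frames <= sw$ends[i]), TRUE)]
  }
  tsp <- matrix(NA_real_, length(sw$roi_ids), length(keep))
  amb <- logical(length(keep))
  for (j in seq_along(keep)) {
    al <- extract_tsp(sw$loadings[, keep[j]], sw$scores[, keep[j]], span = span)
    tsp[, j] <- al$tsp
    amb[j] <- al$ambiguous
  }
  structure(list(events = data.frame(center = sw$centers[keep], start = sw$starts[keep],
                                     end = sw$ends[keep],
                                     explained_variance = v[keep], ambiguous = amb,
                                     sub_cluster = rep(NA_integer_, length(keep))),
                 tsp = tsp, roi_ids = sw$roi_ids, w = sw$w, tr = sw$tr,
                 n_frames = sw$n_frames, frame_offset = sw$frame_offset,
                 subject_id = sw$subject_id, run_id = sw$run_id),
            class = "ts_events")
}

#' @export
print.ts_events <- function(x, ...) {
  cat(sprintf("<ts_events> %d synchronization events (%d ROIs, window %d frames)\n",
              nrow(x$events), length(x$roi_ids), x$w))
  if (nrow(x$events)) {
    ev <- x$events$explained_variance
    cat(sprintf("  explained variance: median %.3f, range %.3f-%.3f\n",
                stats::median(ev), min(ev), max(ev)))
  }
  invisible(x)
}

#' Comparison synchronization measures
#'
#' Per-frame synchronization statistics used in the dynamic-connectivity
#' literature, computed at sliding-window centers for comparison with the
#' explained-variance timecourse:
#' \describe{
#' \item{frobenius_norm}{Frobenius norm of the window correlation matrix
#'   (variance-of-correlation family).}
#' \item{phase_sync}{Kuramoto order parameter of the analytic-signal phases
#'   at the window center frame.}
#' \item{ppa_count}{point-process count: number of ROIs whose full-run
#'   z-scored timecourse exceeds +1 SD at the center frame.}
#' \item{global_efficiency}{mean inverse shortest-path length on the
#'   weighted graph with edge length `1 - r` (bounded by 2 at `r = -1`).
#'   This is the costly measure; it is only computed when requested.}
#' }
#'
#' @param ts a filtered, trimmed [roi_timeseries()].
#' @param w window length in frames (odd).
#' @param measures subset of the four measure names to compute.
#' @return data.frame with `center` (0-based acquisition frame) and one
#'   column per requested measure.
#' @export
sync_measures <- function(ts, w = 25L,
                          measures = c("frobenius_norm", "phase_sync", "ppa_count",
                                       "global_efficiency")) {
  stopifnot(inherits(ts, "roi_ts"))
  measures <- match.arg(measures, several.ok = TRUE)
  win <- sliding_windows(ncol(ts$data), w)
  out <- data.frame(center = win$center + ts$frame_offset)
  n_roi <- nrow(ts$data)
  if ("phase_sync" %in% measures) {
    ph <- apply(ts$data, 1L, function(x) Arg(analytic_signal(x)))  # frames x ROI
    r_t <- Mod(rowMeans(exp(1i * ph)))
    out$phase_sync <- r_t[win$center + 1L]
  }
  if ("ppa_count" %in% measures) {
    z <- t(scale(t(ts$data)))
    out$ppa_count <- colSums(z > 1)[win$center + 1L]
  }
  need_corr <- any(c("frobenius_norm", "global_efficiency") %in% measures)
  if (need_corr) {
    fro <- ge <- rep(NA_real_, nrow(win))
    for (i in seq_len(nrow(win))) {
      z <- window_znorm(ts$data[, (win$start[i] + 1L):(win$end[i] + 1L), drop = FALSE])
      r <- tcrossprod(z) / (w - 1)
      diag(r) <- 1
      if ("frobenius_norm" %in% measures) fro[i] <- sqrt(sum(r^2))
      if ("global_efficiency" %in% measures) {
        len <- pmin(1 - r, 2)
        diag(len) <- 0
        g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                                 weighted = TRUE, diag = FALSE)
        d <- igraph::distances(g)
        ge[i] <- mean(1 / d[upper.tri(d)])
      }
    }
    if ("frobenius_norm" %in% measures) out$frobenius_norm <- fro
    if ("global_efficiency" %in% measures) out$global_efficiency <- ge
  }
  out
}

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Scan detection across window sizes
#'
#' Runs [swpca()] for each requested window size and reports how well the
#' local-maxima positions align with those of the smallest size, to probe
#' the robustness of event timing to the window-length choice.
#'
#' @param ts a filtered, trimmed [roi_timeseries()].
#' @param sizes odd window lengths in frames (e.g. `seq(15, 65, 10)`).
#' @param tol alignment tolerance in frames for matching maxima (default 2).
#' @return list with `scans` (one [swpca()] per size), `maxima` (0-based
#'   center frames of local maxima per size) and `alignment` (data.frame:
#'   size, number of maxima, fraction of reference maxima matched within
#'   `tol`).
#' @export
window_size_scan <- function(ts, sizes, tol = 2L) {
  if (length(sizes) == 0L) stop("window_size_scan: no window sizes given")
  scans <- lapply(sizes, function(w) swpca(ts, w = w))
  names(scans) <- as.character(sizes)
  maxima <- lapply(scans, function(sw) detect_ts(sw)$events$center)
  ref <- maxima[[which.min(sizes)]]
  frac <- vapply(maxima, function(m) {
    if (length(ref) == 0L) return(NA_real_)
    mean(vapply(ref, function(c0) any(abs(m - c0) <= tol), TRUE))
  }, 0)
  list(scans = scans, maxima = maxima,
       alignment = data.frame(size = as.integer(sizes),
                              n_maxima = lengths(maxima),
                              frac_ref_matched = frac, row.names = NULL))
}
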