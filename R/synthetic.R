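# Run code with a local RNG state so generators are deterministic in `seed`
# without disturbing the caller's random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Designed anti-correlated synchronization pattern pairs
#'
#' Builds `2 * n_pairs` ROI-space patterns organized as anti-correlated
#' pairs: within a pair the two patterns correlate at or below -0.8, while
#' patterns from different pairs are nearly uncorrelated (|r| < 0.3). This
#' mirrors the paired sub-cluster structure that transient brain-wide
#' co-activation exhibits (a pattern and its sign-reversed partner). All
#' patterns are mean-zero unit vectors, so Pearson correlation between
#' patterns reduces to their dot product.
#'
#' Construction: one orthonormal mean-zero base direction per pair, each
#' pair's two patterns formed as the base and its negation plus small
#' independent perturbations. The invariants are verified and the draw is
#' retried a bounded number of times; impossible geometries (too few ROIs)
#' fail explicitly.
#'
#' @param n_rois number of ROIs (`>= 2 * n_pairs`).
#' @param n_pairs number of anti-correlated pattern pairs.
#' @param seed integer seed; the same seed reproduces the set exactly.
#' @param perturb_sd perturbation scale controlling how far within-pair
#'   correlation is from -1 (default 0.2, within-pair r about -0.96).
#' @param max_tries retry bound for the invariant check.
#' @return object of class `pattern_set`: `patterns` (ROI x 2*n_pairs
#'   matrix, unit mean-zero columns), `pairing` (data.frame: `pattern`,
#'   `partner`, `pair`), `n_rois`, `n_pairs`, `seed`.
#' @export
make_pattern_set <- function(n_rois, n_pairs, seed = 1L, perturb_sd = 0.2,
                             max_tries = 200L) {
  if (n_rois < 2L * n_pairs)
    stop(sprintf("make_pattern_set: %d ROIs cannot carry %d decorrelated pairs (need >= %d)",
                 n_rois, n_pairs, 2L * n_pairs))
  k <- 2L * n_pairs
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      base <- matrix(stats::rnorm(n_rois * n_pairs), n_rois, n_pairs)
      base <- scale(base, center = TRUE, scale = FALSE)
      qr_q <- qr.Q(qr(base))[, seq_len(n_pairs), drop = FALSE]
      pats <- matrix(0, n_rois, k)
      for (j in seq_len(n_pairs)) {
        for (s in 1:2) {
          v <- (if (s == 1L) 1 else -1) * qr_q[, j] +
            perturb_sd * stats::rnorm(n_rois) / sqrt(n_rois)
          v <- v - mean(v)
          pats[, 2L * (j - 1L) + s] <- v / sqrt(sum(v^2))
        }
      }
      gram <- crossprod(pats)               # = pairwise Pearson r (mean-zero unit columns)
      ok <- TRUE
      for (j in seq_len(n_pairs)) {
        if (gram[2L * j - 1L, 2L * j] > -0.8) ok <- FALSE
      }
      cross <- gram
      for (j in seq_len(n_pairs)) cross[2L * j - 1L, 2L * j] <- cross[2L * j, 2L * j - 1L] <- 0
      diag(cross) <- 0
      if (ok && all(abs(cross) < 0.3)) {
        pairing <- data.frame(pattern = seq_len(k),
                              partner = as.integer(seq_len(k) + c(1L, -1L)),
                              pair = rep(seq_len(n_pairs), each = 2L))
        return(structure(list(patterns = pats, pairing = pairing,
                              n_rois = as.integer(n_rois), n_pairs = as.integer(n_pairs),
                              seed = as.integer(seed)),
                         class = "pattern_set"))
      }
    }
    stop(sprintf("make_pattern_set: could not satisfy pair/decorrelation invariants in %d tries (%d ROIs, %d pairs)",
                 max_tries, n_rois, n_pairs))
  })
}

#' @export
print.pattern_set <- function(x, ...) {
  g <- crossprod(x$patterns)
  wp <- vapply(seq_len(x$n_pairs), function(j) g[2 * j - 1, 2 * j], 0)
  cat(sprintf("<pattern_set> %d pairs (%d patterns) over %d ROIs; within-pair r %.2f to %.2f\n",
              x$n_pairs, 2 * x$n_pairs, x$n_rois, min(wp), max(wp)))
  invisible(x)
}

#' Flank offsets of a bandpassed HRF transient under windowed variance
#'
#' A brain-wide co-activation bump (pattern times the canonical HRF) does
#' not produce one synchronization event but two: the sliding-window
#' variance of the bandpassed transient peaks once on the rising flank
#' (where the window score increases toward the pattern) and once on the
#' falling flank (score increasing toward the sign-reversed pattern). This
#' helper locates both maxima relative to the HRF peak for a given TR,
#' window length and band.
#'
#' @param tr repetition time (seconds).
#' @param window detection window length in frames (odd).
#' @param low_hz,high_hz analysis band (Hz).
#' @return integer vector `c(rise, fall)` of frame offsets from the HRF
#'   peak (rise < 0 < fall).
#' @export
flank_offsets <- function(tr, window = 25L, low_hz = 0.009, high_hz = 0.08) {
  h <- canonical_hrf(tr)
  pk <- which.max(h)
  pad <- 6L * length(h)
  x <- numeric(2L * pad)
  x[(pad - pk + 1L):(pad - pk + length(h))] <- h   # peak at index pad
  bf <- signal::butter(4L, c(low_hz, high_hz) / (1 / (2 * tr)), type = "pass")
  xf <- signal::filtfilt(bf, x)
  hw <- (window - 1L) %/% 2L
  cs <- (pad - 2L * window):(pad + 2L * window)
  v <- vapply(cs, function(c) stats::var(xf[(c - hw):(c + hw)]), 0)
  loc <- which(diff(sign(diff(v))) == -2L) + 1L
  rise <- loc[cs[loc] < pad]
  fall <- loc[cs[loc] >= pad]
  c(rise = cs[rise[which.max(v[rise])]] - pad,
    fall = cs[fall[which.max(v[fall])]] - pad)
}

#' Simulate a resting-state run with known synchronization events
#'
#' Generates an ROI-by-frame BOLD-like run as the sum of (i) transient
#' brain-wide co-activation bumps, each a designed pattern modulated by the
#' canonical double-gamma haemodynamic response, and (ii) Gaussian noise
#' bandpass-filtered to 0.009-0.08 Hz, the band of the preprocessed data
#' the detector operates on. Bump timing is a renewal process; with
#' probability `pair_prob` a bump of the anti-correlated partner pattern
#' follows one window length later.
#'
#' Every bump yields two ground-truth synchronization events, because the
#' sliding-window variance of a bandpassed transient peaks on both flanks
#' (see [flank_offsets()]): a rising-flank event logged under the bump's
#' pattern, and a falling-flank event logged under its anti-correlated
#' partner (the sign rule aligns the detected pattern with the direction of
#' score increase, which reverses across the peak). The event log
#' therefore records, per event, the pattern a correct detector should
#' recover and the frame at which its variance maximum should sit; entries
#' are strictly increasing in time and respect `min_gap` (later events
#' violating it are dropped).
#'
#' SNR is defined as the ratio of the event-component temporal SD to the
#' noise temporal SD, averaged over ROIs. `event_rate` is the expected
#' total number of logged events per frame (two per bump before min-gap
#' enforcement).
#'
#' @param patterns a [make_pattern_set()] result.
#' @param n_frames frames per run (default 1200; `>= 200`).
#' @param tr repetition time in seconds (default 0.72).
#' @param event_rate expected events per frame (default 75/1200).
#' @param snr event-to-noise SD ratio (> 0, `Inf` = noiseless).
#' @param seed integer seed; same seed gives a bit-identical run.
#' @param min_gap minimum frames between consecutive events (default 10).
#' @param pair_prob probability a partner bump follows each primary bump
#'   (default 0.5).
#' @param pair_lag frames between a primary bump and its partner bump
#'   (default 25, one window length).
#' @param window detection window length assumed for the flank geometry.
#' @param amplitude event amplitude in BOLD units (default 1).
#' @param margin frames kept bump-free at the run edges (default 40).
#' @param low_hz,high_hz noise band edges in Hz.
#' @return object of class `synthetic_run`: `roi_ts` (a [roi_timeseries()]),
#'   `log` (data.frame `pattern`, `frame` 0-based, `amplitude`: the
#'   detectable events), `bumps` (underlying transients: `pattern`,
#'   `peak_frame`, `amplitude`), `patterns`, `noise_sd`, `seed`.
#' @export
simulate_run <- function(patterns, n_frames = 1200L, tr = 0.72,
                         event_rate = 75 / 1200, snr = 1, seed = 1L,
                         min_gap = 10L, pair_prob = 0.5, pair_lag = 25L,
                         window = 25L, amplitude = 1, margin = 40L,
                         low_hz = 0.009, high_hz = 0.08) {
  stopifnot(inherits(patterns, "pattern_set"))
  if (n_frames < 200L) stop("simulate_run: need at least 200 frames")
  if (!(snr > 0)) stop("simulate_run: snr must be positive")
  off <- flank_offsets(tr, window, low_hz, high_hz)
  flank_span <- off["fall"] - off["rise"]
  if (pair_lag < flank_span + min_gap)
    pair_lag <- flank_span + min_gap                 # keep within-group events min_gap apart
  gap_min <- flank_span + min_gap                    # keeps inter-bump events apart
  # events per scheduling group = 2 * (1 + pair_prob) on average
  mean_extra <- 2 * (1 + pair_prob) / event_rate - pair_prob * pair_lag - gap_min
  if (mean_extra <= 0)
    stop(sprintf("simulate_run: event_rate %.4g cannot respect a %d-frame minimum gap",
                 event_rate, min_gap))
  with_seed(seed, {
    # renewal process over bump groups: a primary bump, optionally followed by
    # its partner's bump `pair_lag` frames later, then a gap of at least
    # `gap_min` frames before the next group.
    lo <- margin
    hi <- n_frames - 1L - margin
    k <- ncol(patterns$patterns)
    peaks <- integer(0)
    pat <- integer(0)
    g <- lo + stats::rexp(1L, 1 / mean_extra)
    while (g <= hi) {
      p <- sample.int(k, 1L)
      peaks <- c(peaks, g); pat <- c(pat, p)
      last <- g
      if (stats::runif(1L) < pair_prob && g + pair_lag <= hi) {
        peaks <- c(peaks, g + pair_lag)
        pat <- c(pat, patterns$pairing$partner[p])
        last <- g + pair_lag
      }
      g <- last + gap_min + stats::rexp(1L, 1 / mean_extra)
    }
    peaks <- as.integer(round(peaks))
    bumps <- data.frame(pattern = pat, peak_frame = peaks,
                        amplitude = rep(amplitude, length(peaks)))

    sig <- event_signal(patterns$patterns, bumps, n_frames, tr)
    log <- noiseless_event_log(sig, patterns, tr, window, min_gap,
                               low_hz, high_hz, amplitude)
    noise_sd <- 0
    noise <- 0
    if (is.finite(snr)) {
      s_sd <- mean(apply(sig, 1L, stats::sd))
      if (s_sd == 0) s_sd <- amplitude   # event-free run: scale relative to amplitude
      noise_sd <- s_sd / snr
      noise <- band_noise(nrow(sig), n_frames, tr, low_hz, high_hz)
      noise <- noise * (noise_sd / mean(apply(noise, 1L, stats::sd)))
    }
    ts <- roi_timeseries(sig + noise, tr = tr,
                         subject_id = sprintf("sim%03d", seed),
                         run_id = "run1")
    structure(list(roi_ts = ts, log = log, bumps = bumps, patterns = patterns,
                   noise_sd = noise_sd, seed = as.integer(seed),
                   flank_offsets = off,
                   params = list(n_frames = as.integer(n_frames), tr = tr,
                                 event_rate = event_rate, snr = snr, min_gap = min_gap,
                                 pair_prob = pair_prob, pair_lag = pair_lag,
                                 window = as.integer(window), amplitude = amplitude,
                                 margin = margin, low_hz = low_hz, high_hz = high_hz)),
              class = "synthetic_run")
  })
}

# Ground truth = the synchronization events actually present in the
# noiseless signal component: its bandpassed sliding-window variance maxima
# (overlapping transients shift or merge flank maxima, so the schedule alone
# does not define them), each labeled with the designed pattern its signed
# TSP matches best. The bandpass filter rings, so an isolated transient
# trails faint rank-1 echoes that are also strict variance maxima; an
# amplitude floor (window RMS >= amp_floor of the maximum) keeps only
# substantive events. Events closer than min_gap keep the higher-variance
# one.
noiseless_event_log <- function(sig, patterns, tr, window, min_gap,
                                low_hz, high_hz, amplitude, amp_floor = 0.25) {
  ts0 <- bandpass(roi_timeseries(sig, tr = tr), low_hz, high_hz)
  ev0 <- detect_ts(swpca(ts0, w = window))
  if (nrow(ev0$events) == 0L)
    return(data.frame(pattern = integer(0), frame = integer(0), amplitude = numeric(0)))
  hw <- (window - 1L) %/% 2L
  rms <- vapply(ev0$events$center, function(c)
    sqrt(mean(ts0$data[, (c - hw + 1L):(c + hw + 1L)]^2)), 0)
  strong <- rms >= amp_floor * max(rms)
  ev0$events <- ev0$events[strong, , drop = FALSE]
  ev0$tsp <- ev0$tsp[, strong, drop = FALSE]
  sim <- crossprod(tsp_matrix(patterns$patterns), tsp_matrix(ev0))
  pat <- apply(sim, 2L, which.max)
  frame <- ev0$events$center
  v <- ev0$events$explained_variance
  keep <- rep(TRUE, length(frame))
  i_last <- 1L
  for (i in seq_along(frame)[-1L]) {
    if (frame[i] - frame[i_last] < min_gap) {
      if (v[i] > v[i_last]) { keep[i_last] <- FALSE; i_last <- i } else keep[i] <- FALSE
    } else i_last <- i
  }
  data.frame(pattern = as.integer(pat[keep]), frame = frame[keep],
             amplitude = rep(amplitude, sum(keep)))
}

# Sum of HRF-shaped transients: pattern column scaled by `amplitude`,
# kernel peak aligned with the bump's peak frame.
event_signal <- function(patterns, bumps, n_frames, tr) {
  h <- canonical_hrf(tr)
  pk <- which.max(h)
  sig <- matrix(0, nrow(patterns), n_frames)
  for (i in seq_len(nrow(bumps))) {
    f0 <- bumps$peak_frame[i] + 1L - (pk - 1L)   # 1-based column of kernel sample 1
    idx <- f0:(f0 + length(h) - 1L)
    ok <- idx >= 1L & idx <= n_frames
    if (!any(ok)) next
    sig[, idx[ok]] <- sig[, idx[ok]] +
      bumps$amplitude[i] * outer(patterns[, bumps$pattern[i]], h[ok])
  }
  sig
}

# Gaussian white noise filtered to the analysis band (zero-phase).
band_noise <- function(n_roi, n_frames, tr, low_hz, high_hz) {
  nyq <- 1 / (2 * tr)
  bf <- signal::butter(4L, c(low_hz, high_hz) / nyq, type = "pass")
  x <- matrix(stats::rnorm(n_roi * n_frames), n_roi, n_frames)
  t(apply(x, 1L, function(r) signal::filtfilt(bf, r)))
}

#' @export
print.synthetic_run <- function(x, ...) {
  cat(sprintf("<synthetic_run> seed %d: %d events over %d frames (TR %.3g s), noise SD %.3g\n",
              x$seed, nrow(x$log), ncol(x$roi_ts$data), x$roi_ts$tr, x$noise_sd))
  invisible(x)
}

#' Add a voxel-level layer to a synthetic run
#'
#' Each voxel in an ROI's voxel set receives that ROI's full timecourse plus
#' independent bandlimited noise of the run's noise SD (zero if the run is
#' noiseless), so ROI-averaging the voxel data recovers the ROI series up to
#' averaged noise. Voxels not assigned to any ROI carry pure noise. The
#' ground-truth voxel map of any pattern is the pattern broadcast over the
#' voxel sets (see [pattern_voxel_map()]).
#'
#' @param run a [simulate_run()] result.
#' @param roi_to_voxel list (one element per ROI) of disjoint 1-based voxel
#'   index vectors.
#' @param n_voxels total voxel count (`>=` the largest index used).
#' @param seed integer seed for the voxel noise (default derived from the
#'   run's seed).
#' @return the run with `voxel_ts` (voxel x frame matrix) and
#'   `roi_to_voxel` attached.
#' @export
simulate_voxels <- function(run, roi_to_voxel, n_voxels, seed = run$seed + 1L) {
  stopifnot(inherits(run, "synthetic_run"))
  idx <- unlist(roi_to_voxel)
  if (anyDuplicated(idx)) stop("simulate_voxels: voxel sets overlap")
  if (length(idx) && max(idx) > n_voxels)
    stop("simulate_voxels: voxel index exceeds n_voxels")
  if (length(roi_to_voxel) != nrow(run$roi_ts$data))
    stop("simulate_voxels: need one voxel set per ROI")
  n_frames <- ncol(run$roi_ts$data)
  with_seed(seed, {
    vox <- if (run$noise_sd > 0) {
      nz <- band_noise(n_voxels, n_frames, run$roi_ts$tr,
                       run$params$low_hz, run$params$high_hz)
      nz * (run$noise_sd / mean(apply(nz, 1L, stats::sd)))
    } else matrix(0, n_voxels, n_frames)
    for (r in seq_along(roi_to_voxel)) {
      v <- roi_to_voxel[[r]]
      if (length(v))
        vox[v, ] <- vox[v, ] + matrix(run$roi_ts$data[r, ], length(v), n_frames, byrow = TRUE)
    }
    run$voxel_ts <- vox
    run$roi_to_voxel <- roi_to_voxel
    run
  })
}

#' Ground-truth voxel map of an ROI pattern
#'
#' @param pattern ROI-length numeric vector.
#' @param roi_to_voxel list of voxel index vectors per ROI.
#' @param n_voxels total voxel count.
#' @return voxel-length vector with each ROI's pattern value broadcast over
#'   its voxels (0 for unassigned voxels).
#' @export
pattern_voxel_map <- function(pattern, roi_to_voxel, n_voxels) {
  out <- numeric(n_voxels)
  for (r in seq_along(roi_to_voxel)) out[roi_to_voxel[[r]]] <- pattern[r]
  out
}

#' Simulate rigid-body motion parameters
#'
#' Smooth low-amplitude drift (slow sinusoids) in all six parameters plus
#' persistent translation steps of `spike_mm` at the listed frames, emulating
#' abrupt head movements that the FD/scrubbing stage must catch.
#'
#' @param n_frames frames in the run.
#' @param spike_frames 0-based frames at which a head movement occurs.
#' @param spike_mm step size in mm (default 0.6, above the 0.5 FD threshold).
#' @param seed integer seed for the drift phases.
#' @param drift_mm drift amplitude in mm (rotations use `drift_mm / 50` rad;
#'   0 disables drift).
#' @return frames x 6 `motion_trace` matrix (translations mm, rotations rad).
#' @export
simulate_motion <- function(n_frames, spike_frames = integer(0), spike_mm = 0.6,
                            seed = 1L, drift_mm = 0.02) {
  if (length(spike_frames) && (min(spike_frames) < 0L || max(spike_frames) >= n_frames))
    stop("simulate_motion: spike frames outside the run")
  with_seed(seed, {
    t <- seq_len(n_frames)
    m <- sapply(1:6, function(j) {
      amp <- if (j <= 3L) drift_mm else drift_mm / 50
      f <- stats::runif(1L, 0.5, 2) / n_frames     # 0.5-2 cycles per run
      amp * sin(2 * pi * f * t + stats::runif(1L, 0, 2 * pi))
    })
    for (f in spike_frames) m[(f + 1L):n_frames, 1L] <- m[(f + 1L):n_frames, 1L] + spike_mm
    dimnames(m) <- list(NULL, c("tx", "ty", "tz", "rx", "ry", "rz"))
    class(m) <- c("motion_trace", class(m))
    m
  })
}
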