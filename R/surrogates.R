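#' Common-phase randomized surrogate of an ROI time series
#'
#' Adds one shared conjugate-symmetric random phase vector to the discrete
#' Fourier transform of every ROI and inverts. Because every ROI receives
#' the same phases, the surrogate preserves each ROI's power spectrum
#' exactly and all ROI-pair cross-spectra (hence cross-covariance and lagged
#' correlation structure), while destroying any non-stationary event
#' structure -- the stationary null for synchronization-event analyses.
#'
#' @param ts a [roi_timeseries()] (`>= 4` frames).
#' @param seed integer seed for the phase draw.
#' @return surrogate `roi_ts`, same shape and metadata.
#' @export
phase_randomize <- function(ts, seed = 1L) {
  stopifnot(inherits(ts, "roi_ts"))
  n <- ncol(ts$data)
  if (n < 4L) stop("phase_randomize: need at least 4 frames")
  with_seed(seed, {
    m <- (n - 1L) %/% 2L
    phi <- stats::runif(m, 0, 2 * pi)
    rot <- numeric(n)                        # DC (and Nyquist, if present) unchanged
    rot[2:(m + 1L)] <- phi
    rot[n:(n - m + 1L)] <- -phi
    fac <- exp(1i * rot)
    out <- ts
    out$data <- t(apply(ts$data, 1L, function(x)
      Re(stats::fft(stats::fft(x) * fac, inverse = TRUE) / n)))
    out$run_id <- paste0(ifelse(is.na(ts$run_id), "run", ts$run_id), "_surr", seed)
    out
  })
}

#' Internal cluster validity of a TSP partition
#'
#' Ratio of the mean within-cluster correlation distance (`1 - r`) to the
#' mean between-cluster correlation distance; lower values indicate tighter
#' clustering. The mean silhouette width on the same distance is reported
#' alongside as a second interpretation of internal validity. Clusters with
#' fewer than 2 members contribute no within-cluster pairs and are skipped
#' with a warning.
#'
#' @param tsps `ts_events` or ROI x n matrix of TSPs.
#' @param labels cluster labels per pattern.
#' @return list with `ratio` (within/between), `silhouette` (mean width),
#'   `n_used` (patterns in clusters of size >= 2).
#' @export
cluster_validity <- function(tsps, labels) {
  x <- tsp_matrix(tsps)
  labels <- as.integer(labels)
  tab <- table(labels)
  if (sum(tab >= 2L) < 2L)
    stop("cluster_validity: need at least 2 clusters with 2 or more members")
  if (any(tab < 2L)) {
    warning("cluster_validity: skipping singleton clusters: ",
            paste(names(tab)[tab < 2L], collapse = ", "))
    keep <- labels %in% as.integer(names(tab)[tab >= 2L])
    x <- x[, keep, drop = FALSE]
    labels <- labels[keep]
  }
  d <- 1 - crossprod(x)
  same <- outer(labels, labels, `==`)
  ut <- upper.tri(d)
  ratio <- mean(d[ut & same]) / mean(d[ut & !same])
  sil <- cluster::silhouette(labels, dmatrix = d)
  list(ratio = ratio, silhouette = mean(sil[, "sil_width"]), n_used = length(labels))
}

#' Compare real cluster validity against surrogate validity
#'
#' One-sided empirical test of whether the real partition is tighter (lower
#' validity ratio) than partitions obtained from stationary surrogates,
#' with the usual `1/(n+1)` permutation floor, plus a standardized effect
#' size against the null mean and SD.
#'
#' @param real_index validity index of the real data ([cluster_validity()]
#'   `ratio`).
#' @param null_indices numeric vector of surrogate validity indices
#'   (>= 20).
#' @return list with `p` (one-sided empirical p, real tighter than null)
#'   and `effect` ((real - null mean) / null SD).
#' @export
compare_validity <- function(real_index, null_indices) {
  n <- length(null_indices)
  if (n < 20L) stop("compare_validity: need at least 20 null indices")
  p <- (1 + sum(null_indices <= real_index)) / (1 + n)
  list(p = p, effect = (real_index - mean(null_indices)) / stats::sd(null_indices))
}
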