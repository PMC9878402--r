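#' Canonical double-gamma haemodynamic response function
#'
#' The standard canonical HRF: a gamma density with shape 6 and scale 1 s
#' (peak at 5 s) minus one sixth of a gamma density with shape 16 and scale
#' 1 s (the late undershoot), sampled every `tr` seconds over 0-32 s and
#' normalized to unit peak.
#'
#' @param tr sampling interval in seconds (> 0).
#' @return numeric kernel of length `floor(32 / tr) + 1` with attribute
#'   `"peak_time"` (seconds).
#' @export
canonical_hrf <- function(tr) {
  if (!(tr > 0)) stop("canonical_hrf: tr must be positive")
  t <- seq(0, 32, by = tr)
  h <- stats::dgamma(t, shape = 6, scale = 1) - stats::dgamma(t, shape = 16, scale = 1) / 6
  h <- h / max(h)
  attr(h, "peak_time") <- t[which.max(h)]
  h
}

#' Event-coded GLM design matrix
#'
#' One regressor per sub-cluster: a unit impulse at each labeled event's
#' center frame, convolved with the canonical HRF and truncated to the run,
#' plus an intercept. The first and last `trim` frames (50 by convention)
#' are then discarded from the design rows, so a 1,200-frame run yields
#' 1,100 usable rows. Sub-clusters with no events in the run are dropped
#' from the design and recorded.
#'
#' @param events data.frame with 0-based `frame` and integer `sub_cluster`.
#' @param n_frames frames in the run.
#' @param tr repetition time in seconds.
#' @param trim frames discarded at each end of the run (default 50).
#' @param sub_clusters regressor set; defaults to the sorted labels present.
#' @return object of class `design_mat`: `X` (rows = kept frames, columns =
#'   kept sub-cluster regressors + intercept), `frames` (0-based kept frame
#'   indices), `dropped` (labels with zero events), `tr`.
#' @export
build_design <- function(events, n_frames, tr, trim = 50L,
                         sub_clusters = sort(unique(events$sub_cluster))) {
  if (nrow(events) && (min(events$frame) < 0L || max(events$frame) >= n_frames))
    stop("build_design: event frame outside the run")
  h <- canonical_hrf(tr)
  cols <- lapply(sub_clusters, function(sc) {
    imp <- numeric(n_frames)
    f <- events$frame[events$sub_cluster == sc]
    imp[f + 1L] <- 1
    if (!length(f)) return(imp)
    as.numeric(stats::convolve(imp, rev(h), type = "open"))[seq_len(n_frames)]
  })
  n_ev <- vapply(sub_clusters, function(sc) sum(events$sub_cluster == sc), 0L)
  dropped <- sub_clusters[n_ev == 0L]
  if (length(dropped))
    warning("build_design: dropping zero-event regressors: ",
            paste(dropped, collapse = ", "))
  keep <- n_ev > 0L
  X <- do.call(cbind, c(cols[keep], list(rep(1, n_frames))))
  colnames(X) <- c(paste0("sc", sub_clusters[keep]), "intercept")
  if (2L * trim >= n_frames) stop("build_design: trim leaves no frames")
  rows <- seq.int(trim + 1L, n_frames - trim)
  structure(list(X = X[rows, , drop = FALSE], frames = rows - 1L,
                 dropped = sub_clusters[!keep], tr = tr, trim = as.integer(trim)),
            class = "design_mat")
}

#' Per-voxel ordinary least squares GLM
#'
#' Fits every voxel timecourse on the event design by OLS and returns the
#' parameter estimates, residual variance and degrees of freedom. The input
#' matrix must cover the same frames as the design (its `frames` field);
#' a full-frame matrix is subset automatically.
#'
#' @param voxel_ts voxel x frame matrix (frames = full run or exactly the
#'   design rows).
#' @param design a [build_design()] result.
#' @return list with `betas` (voxel x regressor), `sigma2` (residual
#'   variance per voxel), `df` (residual degrees of freedom), `design`.
#' @export
run_glm <- function(voxel_ts, design) {
  stopifnot(inherits(design, "design_mat"))
  X <- design$X
  Y <- as.matrix(voxel_ts)
  if (ncol(Y) != nrow(X)) {
    if (ncol(Y) >= max(design$frames) + 1L) Y <- Y[, design$frames + 1L, drop = FALSE]
    else stop("run_glm: voxel matrix has fewer frames than the design")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("run_glm: design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  betas <- t(qr.coef(qx, t(Y)))
  resid <- Y - betas %*% t(X)
  df <- nrow(X) - ncol(X)
  list(betas = betas, sigma2 = rowSums(resid^2) / df, df = df, design = design)
}

#' Group-level statistics over run-level activation maps
#'
#' Summary-statistics mixed model: run-level beta maps are averaged within
#' subject (runs as fixed effects), then a one-sample t test across subjects
#' (subjects as random effects) is computed per voxel and converted to a
#' z statistic. Voxels with zero between-subject variance produce infinite
#' t values; their z is capped at `z_max` and flagged.
#'
#' @param run_betas list over subjects, each a list over runs of voxel x
#'   sub-cluster beta matrices (identical dimensions throughout).
#' @param z_max cap for the |z| statistic (default 10).
#' @return object of class `sap_group`: `z` (voxel x sub-cluster z map),
#'   `mean_beta`, `n_subjects`, `capped` (logical matrix).
#' @export
group_stats <- function(run_betas, z_max = 10) {
  n_sub <- length(run_betas)
  if (n_sub < 2L) stop("group_stats: need at least 2 subjects")
  subj <- lapply(run_betas, function(runs) Reduce(`+`, runs) / length(runs))
  arr <- simplify2array(subj)                       # voxel x sub-cluster x subject
  mu <- apply(arr, c(1L, 2L), mean)
  sdv <- apply(arr, c(1L, 2L), stats::sd)
  tval <- mu / (sdv / sqrt(n_sub))
  df <- n_sub - 1L
  z <- sign(tval) * stats::qnorm(stats::pt(abs(tval), df, lower.tail = FALSE,
                                           log.p = TRUE),
                                 lower.tail = FALSE, log.p = TRUE)
  capped <- !is.finite(z) | abs(z) > z_max
  z[capped] <- sign(tval[capped]) * z_max
  z[is.na(tval)] <- NA_real_
  structure(list(z = z, mean_beta = mu, n_subjects = n_sub, capped = capped,
                 z_max = z_max),
            class = "sap_group")
}

#' @export
print.sap_group <- function(x, ...) {
  cat(sprintf("<sap_group> %d voxels x %d sub-clusters, %d subjects; mean |z| %.2f (%d capped)\n",
              nrow(x$z), ncol(x$z), x$n_subjects, mean(abs(x$z), na.rm = TRUE),
              sum(x$capped)))
  invisible(x)
}
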